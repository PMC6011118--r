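# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round half away from zero to `digits` decimals (reporting convention:
# 93.0818... -> 93.08, 98.9949... -> 98.99, 0.845 -> 0.85)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TARGET_CHROMS <- c("chr13", "chr18", "chr21")
TRISOMY_LABELS <- c("trisomy13", "trisomy18", "trisomy21")

# "trisomy21" -> "chr21"; "euploid"/"none" -> NA
label_to_chrom <- function(label) {
  ifelse(label %in% TRISOMY_LABELS,
         sub("^trisomy", "chr", label), NA_character_)
}

# "chr21" -> "trisomy21"
chrom_to_label <- function(chrom) sub("^chr", "trisomy", chrom)
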