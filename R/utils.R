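# Internal helpers shared across modules.

# Deterministic sub-seed derivation. All randomness in the package flows from
# one root seed; per-sketch, per-permutation and per-replicate seeds are
# derived with a fixed affine hash kept inside 32-bit integer range.
derive_seed <- function(root, ...) {
  ks <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in ks) s <- (s * 7919 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  force(seed) # before snapshotting: the seed may itself consume ambient RNG
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Canonical string identifier of a model term: "s<i>" for a single SNP,
# "p<i>:<j>" (i < j) for a pair.
term_id <- function(kind, i, j = NA_integer_) {
  if (length(i) == 0L) return(character(0))
  kind <- rep_len(kind, length(i))
  j <- rep_len(j, length(i))
  ifelse(kind == "single", paste0("s", i), paste0("p", i, ":", j))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
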