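# internal helpers shared across modules

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates code as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-ary string hash modulo a Mersenne prime; used to derive
# stable per-association sub-seeds so serial and parallel scoring agree.
stable_hash <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, id) {
  as.integer((seed + stable_hash(id)) %% 2147483646 + 1)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
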