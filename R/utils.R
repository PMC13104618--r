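# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA20, "X")

#' @noRd
check_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop(what, ": invalid amino-acid character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  invisible(seq)
}

# Round half away from zero to `digits` decimals. Base round() uses
# round-half-even, which does not reproduce printed survey percentages
# such as 2.504... -> 2.5 vs 39.13 -> 39.1 consistently at the .x5 boundary.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic substream seeding: every random draw in the package flows
# from one master seed plus a character label, so sub-generators are
# independent of call order. The label is hashed onto [1, 2^31 - 2].
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(paste0("#", label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state.
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
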