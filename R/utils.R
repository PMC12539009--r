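# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a component tag, so each
# generator component draws from its own stream while one master seed
# reproduces everything. Kept below 2^31 - 1.
childSeed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

# Evaluate expr under a local RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Compact-letter display by greedy assignment over a pairwise significance
# matrix: groups not significantly different may share a letter.
assignGroupLetters <- function(groups, sigMatrix) {
  g <- length(groups)
  letters_out <- rep("", g)
  names(letters_out) <- groups
  pools <- list()  # each pool: set of group indices sharing a letter
  for (i in seq_len(g)) {
    placed <- FALSE
    for (p in seq_along(pools)) {
      if (all(!sigMatrix[i, pools[[p]]])) {
        pools[[p]] <- c(pools[[p]], i)
        placed <- TRUE
      }
    }
    if (!placed) pools[[length(pools) + 1L]] <- i
  }
  for (p in seq_along(pools))
    for (i in pools[[p]])
      letters_out[i] <- paste0(letters_out[i], letters[p])
  letters_out
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
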