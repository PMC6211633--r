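DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `A,C,G,T,N,-` (case is
#' preserved for lower-case input).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTN")  # "NACGT"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_seq <- function(ch) paste(ch, collapse = "")

# substitute each base in `ch[idx]` by a uniformly chosen different base
mutate_bases <- function(ch, idx) {
  if (length(idx) == 0L) return(ch)
  for (i in idx) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  ch
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package log level
#'
#' Pipeline stages log input counts, filter counts and active seeds through a
#' simple leveled logger.  The active level is the option
#' `chimerapop.log_level` (one of `"debug"`, `"info"`, `"warn"`, `"error"`;
#' default `"info"`).
#'
#' @param level message level.
#' @param ... passed to [sprintf()].
#' @return invisibly, the formatted message.
#' @export
cp_log <- function(level = "info", ...) {
  lv <- .log_levels[[match.arg(level, names(.log_levels))]]
  active <- .log_levels[[getOption("chimerapop.log_level", "info")]]
  msg <- sprintf(...)
  if (lv >= active) message(sprintf("[%s] %s", toupper(level), msg))
  invisible(msg)
}
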