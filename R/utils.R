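# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific 32-bit seed from a master seed, so that pipeline
# stages draw from independent, reproducible streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

#' @noRd
msg <- function(..., verbose = getOption("shapesig.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[shapesig] ", ...)
}

# Jaccard index between two character sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Best-match Jaccard overlap between two module partitions
#'
#' For each reference module, finds the detected module with the highest
#' Jaccard index. Used to score recovery of planted coexpression modules.
#'
#' @param detected named list of character vectors (detected modules).
#' @param truth named list of character vectors (reference modules).
#' @return data.frame with columns `truth_module`, `best_match`, `jaccard`.
#' @export
best_match_jaccard <- function(detected, truth) {
  if (length(truth) == 0L) stop("no reference modules")
  res <- lapply(names(truth), function(tm) {
    if (length(detected) == 0L) {
      return(data.frame(truth_module = tm, best_match = NA_character_,
                        jaccard = 0, stringsAsFactors = FALSE))
    }
    js <- vapply(detected, function(d) jaccard(d, truth[[tm]]), numeric(1))
    data.frame(truth_module = tm, best_match = names(detected)[which.max(js)],
               jaccard = max(js), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Stop unless all conditions hold, with a readable message.
check_that <- function(cond, message) {
  if (!isTRUE(cond)) stop(message, call. = FALSE)
}
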