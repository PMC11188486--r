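#' Derive a reproducible child seed from labelled components
#'
#' Folds a master seed together with an arbitrary set of labels (scenario,
#' cell, relationship, repetition, ...) into a deterministic integer seed.
#' Used throughout the benchmark so that every simulated repetition and every
#' model fit is reproducible from one master seed, while distinct records get
#' distinct streams.
#'
#' @param master integer master seed.
#' @param ... further components (coerced to character) identifying the record.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(42, "scenario1", 0.2, "linear", 7)
#' @export
deriveSeed <- function(master, ...) {
  key <- paste(c(master, vapply(list(...), as.character, character(1))),
               collapse = "\r")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483629
  as.integer(h %% 2147483645L + 1L)
}

# shared argument checks -----------------------------------------------------

.checkCountMatrix <- function(m, what = "counts") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (anyNA(m)) stop(what, " contains missing values")
  if (any(m < 0)) stop(what, " contains negative values")
  if (any(abs(m - round(m)) > 1e-8)) stop(what, " contains non-integer values")
  invisible(m)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.geomMean <- function(x) exp(mean(log(x)))

.rowVars <- function(m) {
  nc <- ncol(m)
  if (nc < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (nc - 1)
}
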