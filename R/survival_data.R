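#' Construct a censored survival dataset
#'
#' Bundles follow-up times, censoring indicators, a covariate matrix and the
#' administrative follow-up horizon `tau` into a single validated object.
#' `tau` defines the binary outcome the SVM trainers classify: event by `tau`
#' (+1) versus event-free at `tau` (-1).
#'
#' @param time Non-negative numeric vector of observed times (time to event or
#'   to censoring).
#' @param status Integer vector in \{0, 1\}; 0 = censored, 1 = event.
#' @param x Numeric covariate matrix with one row per observation.
#' @param tau Positive administrative follow-up horizon. Defaults to
#'   `max(time)`. Must be at least the maximum observed time.
#'
#' @return An object of class `survival_dataset`: a list with elements `time`,
#'   `status`, `x` (matrix) and `tau`.
#' @export
#' @examples
#' d <- survival_dataset(c(3, 7, 18), c(1, 0, 0), matrix(rnorm(6), 3), tau = 18)
#' d
survival_dataset <- function(time, status, x, tau = max(time)) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) == 0L) stop("empty dataset")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and non-negative")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 (censored) or 1 (event)")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(time)) stop("x must have one row per observation")
  if (length(status) != length(time)) stop("time and status lengths differ")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) stop("tau must be a positive scalar")
  if (tau < max(time)) stop("tau must be >= max observed time; truncate first")
  structure(list(time = time, status = status, x = x, tau = tau),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("survival_dataset: %d observations, %d covariates, tau = %g\n",
              n, ncol(x$x), x$tau))
  b <- binarize(x)
  cat(sprintf("  events: %d  nonevents: %d  censored before tau: %d\n",
              length(b$events), length(b$nonevents), length(b$censored)))
  invisible(x)
}

#' Partition a survival dataset into events, nonevents and censored
#'
#' Events are observations with `status == 1` and `time <= tau`; nonevents
#' completed follow-up event-free (`time >= tau`, regardless of status);
#' censored observations left the study before `tau` without an event. The
#' partition is exhaustive and disjoint. Package-wide class coding is
#' y = +1 for event, y = -1 for nonevent.
#'
#' @param data A [survival_dataset].
#' @return List with integer index vectors `events`, `nonevents`, `censored`
#'   and a vector `y` (+1 / -1 / `NA` for censored).
#' @export
binarize <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  ev <- data$status == 1L & data$time <= data$tau
  ne <- !ev & data$time >= data$tau
  cs <- !ev & !ne
  y <- ifelse(ev, 1, ifelse(ne, -1, NA))
  list(events = which(ev), nonevents = which(ne), censored = which(cs), y = y)
}

#' Read a survival table from CSV
#'
#' Expects a header with columns `time` (numeric) and `status` (0/1); every
#' remaining numeric column is treated as a covariate.
#'
#' @param path CSV file path.
#' @param tau Administrative horizon; defaults to the maximum observed time.
#' @return A [survival_dataset].
#' @export
read_survival_csv <- function(path, tau = NULL) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("time", "status") %in% names(df)))
    stop("CSV must contain 'time' and 'status' columns")
  covar <- df[, setdiff(names(df), c("time", "status")), drop = FALSE]
  x <- as.matrix(covar)
  if (is.null(tau)) tau <- max(df$time)
  survival_dataset(df$time, df$status, x, tau = tau)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_csv()]; `tau` is not stored in the file.
#'
#' @param data A [survival_dataset].
#' @param path Output path.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  x <- data$x
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(time = data$time, status = data$status, x,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
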