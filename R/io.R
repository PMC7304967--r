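#' Read and write trial tables and design matrices as delimited text
#'
#' Trial/event tables and design matrices travel as tab-delimited text with a
#' single header line, so cohorts and regressors can be exchanged with other
#' tools. \code{write_design} stores the repetition time and run index as
#' leading columns \code{frame_time} and \code{run}.
#'
#' @param trials,design object to write.
#' @param path file path.
#' @return The read functions return a data frame (trials) or a list with
#'   \code{X}, \code{frame_times}, \code{run} (design); the write functions
#'   return \code{path} invisibly.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_trials
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "savor_design"))
  out <- data.frame(frame_time = design$frame_times, run = design$run,
                    design$X, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_design <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  list(X = as.matrix(d[, -(1:2), drop = FALSE]),
       frame_times = d$frame_time, run = d$run)
}

#' Serialize a hierarchical fit to JSON
#'
#' Stores the group prior, per-subject MAP estimates and Laplace variances,
#' the EM trace, seed and control settings in a structured text file;
#' \code{read_savor_fit} restores them as plain lists (not a re-usable
#' \code{savor_fit} object — refit for that).
#'
#' @param fit a \code{\link{fit_savor}} result.
#' @param path file path.
#' @export
write_savor_fit <- function(fit, path) {
  obj <- list(
    model = fit$model$name,
    prior = list(mean = as.list(fit$prior$mean),
                 var = as.list(fit$prior$var)),
    subjects = lapply(fit$subjects, function(f)
      list(map = as.list(f$m), laplace_var = as.list(diag(f$Sigma)),
           log_post = f$log_post,
           params = as.list(unlist(f$params)))),
    trace = fit$trace, converged = fit$converged,
    n_trials = fit$n_trials, seed = fit$seed,
    control = unclass(fit$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_savor_fit
#' @export
read_savor_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
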