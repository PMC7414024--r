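# CSV dialects: comma-separated, UTF-8, dot decimal, mandatory header;
# times in seconds, amounts in molecules/cell.

#' Export a time course as tidy CSV
#'
#' Columns `time`, `species`, `amount`.
#'
#' @param tc a `pi_timecourse`.
#' @param path destination.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-import a tidy time-course CSV
#'
#' @param path a file written by [write_timecourse_csv()].
#' @return a `pi_timecourse` (no binding-pair map: observables are the raw
#'   columns present).
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "species", "amount") %in% names(d)))
    stop("time-course CSV must have columns time, species, amount")
  sp <- unique(d$species)
  times <- sort(unique(d$time))
  am <- matrix(NA_real_, length(times), length(sp),
               dimnames = list(NULL, sp))
  for (s in sp) {
    ds <- d[d$species == s, ]
    am[match(ds$time, times), s] <- ds$amount
  }
  tc <- structure(list(times = times, amounts = am, binding_pairs = NULL),
                  class = "pi_timecourse")
  tc$observables <- observable_matrix(tc)
  tc
}

#' Proteome CSV I/O
#'
#' Strict dialect: header `cell_type,protein,copies_per_cell,provenance`.
#'
#' @param proteome a [proteome_table()] (possibly several cell types bound
#'   together).
#' @param path file path.
#' @rdname proteome_csv
#' @export
write_proteome_csv <- function(proteome, path) {
  utils::write.csv(as.data.frame(proteome), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @param cell_type if given, filter the file to one cell type.
#' @rdname proteome_csv
#' @export
read_proteome_csv <- function(path, cell_type = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "protein", "copies_per_cell", "provenance")
  if (!identical(names(d), need))
    stop("proteome CSV must have exactly the header ",
         paste(need, collapse = ","))
  if (!is.null(cell_type)) d <- d[d$cell_type == cell_type, ]
  structure(d, class = c("pi_proteome", "data.frame"))
}

#' Experimental-dataset CSV I/O
#'
#' Columns `observable,time,mean,sem,n`: time-resolved means and dispersion
#' per observable, the calibration target format.
#'
#' @param data the dataset data.frame.
#' @param path file path.
#' @rdname dataset_csv
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(data[, c("observable", "time", "mean", "sem", "n")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_csv
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "time", "mean", "sem", "n")
  if (!all(need %in% names(d)))
    stop("dataset CSV must have columns ", paste(need, collapse = ","))
  if (any(d$sem < 0)) stop("sem must be >= 0")
  if (any(d$n < 1)) stop("n must be >= 1")
  d[order(d$observable, d$time), need]
}

#' Export a parameter-scan report
#'
#' @param results a [scan_parameter()] result.
#' @param path file path.
#' @export
write_scan_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
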