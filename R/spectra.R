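#' Construct an isotopologue spectrum
#'
#' A mass isotopomer distribution (MID) for one metabolite in one sample:
#' the abundances of the isotopologues M+0 .. M+C, where C is the number of
#' carbon atoms and M+i carries i heavy (13C) atoms. Values may be raw
#' LC-MS intensities (`is_fraction = FALSE`) or fractional abundances
#' summing to 1 (`is_fraction = TRUE`).
#'
#' @param metabolite metabolite name (e.g. `"lactate"`).
#' @param values numeric vector of length `carbon_count + 1`, the abundances
#'   of M+0 .. M+C in order. Must be non-negative.
#' @param carbon_count integer number of carbon atoms C (>= 1). Defaults to
#'   `length(values) - 1`.
#' @param is_fraction logical; are `values` fractional abundances summing
#'   to 1?
#' @param sample optional sample identifier carried along for bookkeeping.
#' @return An object of class `"isotopologue_spectrum"`: a list with fields
#'   `metabolite`, `carbon_count`, `values`, `is_fraction`, `sample`.
#' @examples
#' isotopologue_spectrum("lactate", c(0.5, 0.25, 0.25, 0), is_fraction = TRUE)
#' @export
isotopologue_spectrum <- function(metabolite, values,
                                  carbon_count = length(values) - 1L,
                                  is_fraction = FALSE, sample = NA_character_) {
  carbon_count <- as.integer(carbon_count)
  values <- as.numeric(values)
  if (carbon_count < 1L)
    stop("carbon_count must be >= 1", call. = FALSE)
  if (length(values) != carbon_count + 1L)
    stop(sprintf("expected %d isotopologue values (M+0..M+%d), got %d",
                 carbon_count + 1L, carbon_count, length(values)), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("isotopologue values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("isotopologue values must be non-negative", call. = FALSE)
  if (isTRUE(is_fraction) && abs(sum(values) - 1) > 1e-9)
    stop(sprintf("fractional spectrum for %s must sum to 1 (got %.12g)",
                 metabolite, sum(values)), call. = FALSE)
  structure(
    list(metabolite = as.character(metabolite), carbon_count = carbon_count,
         values = values, is_fraction = isTRUE(is_fraction),
         sample = as.character(sample)),
    class = "isotopologue_spectrum")
}

#' @export
print.isotopologue_spectrum <- function(x, ...) {
  kind <- if (x$is_fraction) "fractions" else "intensities"
  cat(sprintf("Isotopologue spectrum: %s (C = %d, %s)\n",
              x$metabolite, x$carbon_count, kind))
  if (!is.na(x$sample)) cat(sprintf("  sample: %s\n", x$sample))
  v <- x$values
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(signif(v, 6))
  invisible(x)
}

#' Convert a raw spectrum to fractional abundances
#'
#' Divides the isotopologue abundances by their sum so they describe the
#' mass isotopomer distribution as fractions summing to 1. Idempotent.
#'
#' @param spec an [isotopologue_spectrum()].
#' @return The spectrum with `values` summing to 1 and `is_fraction = TRUE`.
#' @examples
#' s <- isotopologue_spectrum("lactate", c(2, 1, 1, 0))
#' to_fractions(s)$values  # 0.5 0.25 0.25 0
#' @export
to_fractions <- function(spec) {
  stopifnot(inherits(spec, "isotopologue_spectrum"))
  tot <- sum(spec$values)
  if (tot <= 0)
    stop(sprintf("all-zero spectrum for %s (sample %s): cannot normalize",
                 spec$metabolite, spec$sample), call. = FALSE)
  spec$values <- spec$values / tot
  spec$is_fraction <- TRUE
  spec
}

#' Read an isotopologue intensity table
#'
#' Reads a CSV of raw isotopologue intensities with header columns
#' `sample, metabolite, carbon_count, isotopologue_index, intensity`
#' (comma-delimited, decimal point, UTF-8) and assembles one spectrum per
#' (sample, metabolite). Isotopologue indices absent from the table are
#' zero-filled with a warning, since LC-MS exports commonly omit undetected
#' species. Duplicate (sample, metabolite, index) rows, or an index larger
#' than the metabolite's carbon count, are hard errors.
#'
#' @param path path to the CSV file, or a data frame with the same columns.
#' @return A named list of class `"isotopologue_set"`; element names are
#'   `"<sample>::<metabolite>"` and each element is an
#'   [isotopologue_spectrum()] with `is_fraction = FALSE`.
#' @export
read_isotopologue_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample", "metabolite", "carbon_count", "isotopologue_index",
            "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("isotopologue table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(tab$sample, tab$metabolite, tab$isotopologue_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate isotopologue row: sample %s, metabolite %s, index M+%d",
      d$sample, d$metabolite, d$isotopologue_index), call. = FALSE)
  }
  bad <- tab$isotopologue_index > tab$carbon_count | tab$isotopologue_index < 0
  if (any(bad)) {
    d <- tab[bad, , drop = FALSE][1L, ]
    stop(sprintf(
      "isotopologue index M+%d exceeds carbon count %d (sample %s, metabolite %s)",
      d$isotopologue_index, d$carbon_count, d$sample, d$metabolite),
      call. = FALSE)
  }
  groups <- split(tab, paste(tab$sample, tab$metabolite, sep = "\r"), drop = TRUE)
  out <- vector("list", length(groups))
  nms <- character(length(groups))
  filled <- character(0)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    C <- unique(rows$carbon_count)
    if (length(C) != 1L)
      stop(sprintf("inconsistent carbon_count for sample %s, metabolite %s",
                   rows$sample[1L], rows$metabolite[1L]), call. = FALSE)
    vals <- numeric(C + 1L)
    vals[rows$isotopologue_index + 1L] <- rows$intensity
    if (nrow(rows) < C + 1L)
      filled <- c(filled, sprintf("%s/%s", rows$sample[1L], rows$metabolite[1L]))
    out[[g]] <- isotopologue_spectrum(rows$metabolite[1L], vals,
                                      carbon_count = C, is_fraction = FALSE,
                                      sample = rows$sample[1L])
    nms[g] <- paste(rows$sample[1L], rows$metabolite[1L], sep = "::")
  }
  if (length(filled))
    warning("zero-filled missing isotopologue indices for: ",
            paste(filled, collapse = ", "), call. = FALSE)
  names(out) <- nms
  structure(out, class = "isotopologue_set")
}

#' Read a tracer metadata table
#'
#' Reads the table declaring which tracer was infused in which experiment
#' and which samples (animals) belong to it. Required columns:
#' `experiment, tracer_metabolite, tracer_carbons, sample, group`.
#'
#' @param path path to the CSV file, or a data frame with those columns.
#' @return A data frame with one row per (experiment, sample).
#' @export
read_tracer_metadata <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("experiment", "tracer_metabolite", "tracer_carbons", "sample",
            "group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tracer metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Write a contribution result to CSV
#'
#' Exports the non-negative contribution fractions and their Monte Carlo
#' standard errors as a CSV with columns
#' `substrate, fraction, se, n_monte_carlo`, floats printed to 12
#' significant digits so the file round-trips through
#' [utils::read.csv()] losslessly.
#'
#' @param result a `"contribution_result"` (see [solve_contributions()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "contribution_result"))
  k <- length(result$substrates)
  df <- data.frame(substrate = result$substrates,
                   fraction = format_sig(result$f),
                   se = format_sig(result$f_se),
                   n_monte_carlo = rep(result$n_mc, k),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-format float printing: 12 significant digits, C locale semantics
format_sig <- function(x) {
  if (!length(x)) return(character(0))
  formatC(x, digits = 12, format = "g", flag = "")
}
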