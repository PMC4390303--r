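# Radionuclide decay data for the internal blood-irradiation model.
# Each bundled file carries a binned beta spectrum, discrete conversion and
# Auger electron lines, and gamma/X-ray lines, with per-decay yields.

nuclide_data_dir <- function() {
  system.file("extdata", "nuclides", package = "rifcalib")
}

#' Nuclides bundled with the package
#'
#' @return character vector of nuclide identifiers that [load_nuclide()]
#'   accepts without an explicit file path.
#' @export
available_nuclides <- function() {
  sub("\\.tsv$", "", list.files(nuclide_data_dir(), pattern = "\\.tsv$"))
}

#' Load decay data for a radionuclide
#'
#' Reads a bundled (or user-supplied) decay-data file into a `nuclide`
#' object holding the half-life, the electron emission inventory (binned
#' beta spectrum plus conversion/Auger lines) and the photon lines.  The
#' electron inventory deliberately includes the non-beta electrons: for
#' both I-131 and Lu-177 conversion and Auger electrons add several keV
#' per decay on top of the mean beta energy, which is not negligible for
#' the blood S-value.
#'
#' @param name nuclide identifier, e.g. `"I-131"` or `"Lu-177"`.
#' @param path optional path to a decay-data file in the bundled format
#'   (tab-separated columns `kind`, `energy_keV`, `yield_per_decay`, a
#'   `# half_life_days:` header line); overrides `name` lookup.
#' @return object of class `nuclide` with elements `name`, `half_life`
#'   (seconds), `electrons` (data.frame `kind`, `energy`, `yield`) and
#'   `photons` (data.frame `energy`, `yield`).
#' @examples
#' iodine <- load_nuclide("I-131")
#' decay_constant(iodine)
#' @export
load_nuclide <- function(name, path = NULL) {
  if (is.null(path)) {
    known <- available_nuclides()
    if (!name %in% known)
      stop("unknown nuclide '", name, "'; available: ",
           paste(known, collapse = ", "))
    path <- file.path(nuclide_data_dir(), paste0(name, ".tsv"))
  }
  lines <- readLines(path)
  hl_line <- grep("^# half_life_days:", lines, value = TRUE)
  if (length(hl_line) != 1)
    stop("malformed decay-data file ", path,
         ": expected exactly one '# half_life_days:' header line")
  half_life_d <- as.numeric(sub("^# half_life_days:\\s*", "", hl_line))

  is_data <- !grepl("^#", lines) & nzchar(lines)
  data_idx <- which(is_data)
  tab <- utils::read.delim(textConnection(lines[is_data]),
                           stringsAsFactors = FALSE)
  need <- c("kind", "energy_keV", "yield_per_decay")
  if (!all(need %in% names(tab)))
    stop("malformed decay-data file ", path, ": expected columns ",
         paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$energy_keV) | !is.finite(tab$yield_per_decay) |
                 tab$energy_keV <= 0 | tab$yield_per_decay < 0)
  if (length(bad))
    stop("malformed decay-data file ", path, " at line ",
         data_idx[bad[1] + 1], ": non-numeric, non-positive energy or ",
         "negative yield")
  known_kinds <- c("beta_spectrum_bin", "conversion_or_auger", "photon")
  if (!all(tab$kind %in% known_kinds))
    stop("malformed decay-data file ", path, ": unknown emission kind '",
         setdiff(tab$kind, known_kinds)[1], "'")

  el <- tab[tab$kind != "photon", ]
  ph <- tab[tab$kind == "photon", ]
  structure(list(
    name = if (is.null(name)) basename(path) else name,
    half_life = half_life_d * 86400,
    electrons = data.frame(kind = el$kind, energy = el$energy_keV,
                           yield = el$yield_per_decay),
    photons = data.frame(energy = ph$energy_keV, yield = ph$yield_per_decay)
  ), class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s>  T1/2 = %.3f d,  lambda = %.4g /s\n",
              x$name, x$half_life / 86400, decay_constant(x)))
  cat(sprintf("  electrons: %d emissions, %.1f keV/decay (beta mean %.1f keV)\n",
              nrow(x$electrons), emitted_energy_per_decay(x, "electrons"),
              mean_beta_energy(x)))
  cat(sprintf("  photons:   %d lines, %.1f keV/decay\n",
              nrow(x$photons), emitted_energy_per_decay(x, "photons")))
  invisible(x)
}

#' Decay constant
#'
#' @param nuclide a `nuclide` object.
#' @return lambda = ln(2) / half-life, in s^-1.
#' @export
decay_constant <- function(nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (nuclide$half_life <= 0) stop("half-life must be positive")
  log(2) / nuclide$half_life
}

#' Yield-weighted emitted energy per decay
#'
#' Sum of energy times yield over one emission channel; the full-local-
#' absorption S-value bound and the Monte Carlo tallies both build on it.
#'
#' @param nuclide a `nuclide` object.
#' @param channel `"electrons"` (beta spectrum plus conversion/Auger) or
#'   `"photons"`.
#' @return keV per decay (0 for an empty channel).
#' @export
emitted_energy_per_decay <- function(nuclide,
                                     channel = c("electrons", "photons")) {
  stopifnot(inherits(nuclide, "nuclide"))
  channel <- match.arg(channel)
  tab <- nuclide[[channel]]
  if (nrow(tab) == 0) return(0)
  sum(tab$energy * tab$yield)
}

# beta-spectrum summaries used by validity checks and tests
#' @rdname emitted_energy_per_decay
#' @export
mean_beta_energy <- function(nuclide) {
  b <- nuclide$electrons[nuclide$electrons$kind == "beta_spectrum_bin", ]
  if (nrow(b) == 0) return(NA_real_)
  sum(b$energy * b$yield) / sum(b$yield)
}

#' @rdname emitted_energy_per_decay
#' @export
max_beta_energy <- function(nuclide) {
  b <- nuclide$electrons[nuclide$electrons$kind == "beta_spectrum_bin", ]
  if (nrow(b) == 0) return(NA_real_)
  max(b$energy)
}
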