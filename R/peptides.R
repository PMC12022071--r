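#' @keywords internal
"_PACKAGE"

#' Canonical amyloid-beta 1-42 sequence
#'
#' One-letter amino-acid sequence of human A\eqn{\beta}1-42, the parent of
#' every truncated/modified species in the panel.
#' @format A length-one character string (42 residues).
#' @export
ABETA42_SEQUENCE <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

# Average (not monoisotopic) residue masses in Da. Linear-mode TOF at
# m/dm = 1000 does not resolve isotopes, so average masses are the right
# convention for the observed centroid.
.residue_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.mass_water  <- 18.0153
.mass_proton <- 1.008

#' Build an amyloid-beta peptide panel
#'
#' Parses peptide names of the form `"Abeta<start>[pE]-<end>"` (e.g.
#' `"Abeta1-42"`, `"Abeta3pE-40"`), extracts the corresponding slice of the
#' canonical A\eqn{\beta}1-42 sequence, and computes average neutral masses
#' and observed \eqn{[M+H]^+} m/z values.
#'
#' Pyroglutamate (`pE`) formation at the N-terminus is only chemically
#' possible when the first residue of the slice is glutamate (E, water loss,
#' -18.02 Da) or glutamine (Q, ammonia loss, -17.03 Da).
#'
#' @param panel_names character vector of peptide names.
#' @return A data frame with one row per peptide: `name`, `start`, `end`,
#'   `pyroglu`, `sequence`, `neutral_avg_mass`, `mz_obs`.
#' @examples
#' build_abeta_panel(c("Abeta1-42", "Abeta1-40", "Abeta3pE-42"))
#' @export
build_abeta_panel <- function(panel_names) {
  stopifnot(is.character(panel_names), length(panel_names) >= 1)
  rows <- lapply(panel_names, .parse_abeta_name)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- out$mz_obs < 1500 | out$mz_obs > 6000
  if (any(bad)) {
    stop("peptide(s) outside the 1500-6000 Da acquisition range: ",
         paste(out$name[bad], collapse = ", "))
  }
  out
}

.parse_abeta_name <- function(name) {
  m <- regmatches(name, regexec("^Abeta([0-9]+)(pE)?-([0-9]+)$", name))[[1]]
  if (length(m) == 0) {
    stop("cannot parse peptide name '", name,
         "': expected Abeta<start>[pE]-<end>, e.g. 'Abeta3pE-42'")
  }
  start <- as.integer(m[2]); end <- as.integer(m[4])
  pyroglu <- m[3] == "pE"
  if (!(start >= 1 && start < end && end <= 42)) {
    stop("invalid residue range in '", name, "': need 1 <= start < end <= 42")
  }
  seq42 <- strsplit(ABETA42_SEQUENCE, "")[[1]]
  residues <- seq42[start:end]
  if (pyroglu && !(residues[1] %in% c("E", "Q"))) {
    stop("pyroglutamate in '", name, "' requires an N-terminal E or Q, but ",
         "residue ", start, " of Abeta1-42 is '", residues[1], "'")
  }
  unknown <- setdiff(residues, names(.residue_avg_mass))
  if (length(unknown) > 0) stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  mass <- sum(.residue_avg_mass[residues]) + .mass_water
  if (pyroglu) {
    mass <- mass - if (residues[1] == "E") .mass_water else 17.0265
  }
  data.frame(
    name = name, start = start, end = end, pyroglu = pyroglu,
    sequence = paste(residues, collapse = ""),
    neutral_avg_mass = mass, mz_obs = mass + .mass_proton,
    stringsAsFactors = FALSE
  )
}

#' Default amyloid-beta peptide panel
#'
#' The nine A\eqn{\beta} species tracked throughout the analysis: the
#' full-length, N-terminally truncated and pyroglutamated x-40 and x-42
#' forms that discriminate plaque morphotypes.
#' @return See [build_abeta_panel()].
#' @export
default_abeta_panel <- function() {
  build_abeta_panel(c(
    "Abeta1-40", "Abeta1-42", "Abeta2-42", "Abeta3pE-40", "Abeta3pE-42",
    "Abeta4-40", "Abeta4-42", "Abeta5-42", "Abeta11pE-42"
  ))
}
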