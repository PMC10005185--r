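#' @keywords internal
"_PACKAGE"

# IUPAC 2021 standard atomic weights (conventional values) for the element
# subset the pipeline supports.  Da.
.ag_atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

# Bondi van der Waals radii, Angstrom.  Elements absent from Bondi's table
# fall back to 1.70.
.ag_vdw_radius <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92,
  Na = 2.27, Mg = 1.73, K = 2.75, Ca = 2.31
)

# Allowed valences per neutral element, used to derive implicit hydrogen
# counts from the explicit bond graph (smallest allowed valence that is
# >= the bond-order sum wins).
.ag_valences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, Na = 0, Mg = 0, K = 0, Ca = 0
)

.ag_supported_elements <- names(.ag_atomic_mass)

#' Van der Waals radius lookup
#'
#' Returns Bondi van der Waals radii for a vector of element symbols.
#' Unknown-but-supported elements fall back to 1.70 Angstrom.
#'
#' @param element character vector of element symbols.
#' @param table optional named numeric vector overriding the built-in radii.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, table = NULL) {
  tab <- .ag_vdw_radius
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[element])
  r[is.na(r)] <- 1.70
  r
}

.ag_check_elements <- function(element, where = "molecule") {
  bad <- which(!(element %in% .ag_supported_elements))
  if (length(bad)) {
    stop(sprintf("unsupported element '%s' at atom index %d in %s",
                 element[bad[1]], bad[1], where), call. = FALSE)
  }
  invisible(TRUE)
}
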