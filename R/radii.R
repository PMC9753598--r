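# Element metadata: bundled covalent radii (Cordero-type single-bond values,
# Z = 1..86; low-spin values for Mn, Fe, Co) and the metal classification used
# by bond perception.

.reanet_env <- new.env(parent = emptyenv())

.radius_table <- function() {
  if (is.null(.reanet_env$radii)) {
    path <- system.file("extdata", "covalent_radii.csv", package = "reanet")
    if (path == "") { # not installed yet (e.g. pkgload); fall back to source tree
      path <- file.path("inst", "extdata", "covalent_radii.csv")
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .reanet_env$radii <- stats::setNames(tab$radius, tab$symbol)
    .reanet_env$z <- stats::setNames(tab$z, tab$symbol)
  }
  .reanet_env$radii
}

#' Covalent radius of an element
#'
#' Returns the bundled single-bond covalent radius (Cordero-type values,
#' elements H through Rn). Bond perception cutoffs are scale factors applied
#' to sums of these radii.
#'
#' @param element Character vector of element symbols (case-sensitive, e.g.
#'   `"Mn"`).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' covalent_radius("H")
#' covalent_radius(c("C", "O", "Mn"))
#' @export
covalent_radius <- function(element) {
  tab <- .radius_table()
  r <- tab[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         ". Supported symbols: ", paste(names(tab), collapse = " "))
  }
  unname(r)
}

.atomic_number <- function(element) {
  .radius_table() # ensure loaded
  z <- .reanet_env$z[element]
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(element[is.na(z)]), collapse = ", "))
  unname(z)
}

# d-block elements: Sc-Zn, Y-Cd, La, Hf-Hg
.TRANSITION_METALS <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

.ALKALI <- c("Li", "Na", "K", "Rb", "Cs")
.ALKALINE_EARTH <- c("Be", "Mg", "Ca", "Sr", "Ba")
.HALOGENS <- c("F", "Cl", "Br", "I", "At")

#' Is an element a transition metal?
#'
#' Transition metals (the d-block) are the organometallic bonding centers and
#' the default pivot atoms of fragment analysis. Alkali and alkaline-earth
#' metals are treated as ionic-only centers, not transition metals.
#'
#' @param element Character vector of element symbols.
#' @return Logical vector.
#' @export
is_transition_metal <- function(element) element %in% .TRANSITION_METALS

.is_ionic_center <- function(element) element %in% c(.ALKALI, .ALKALINE_EARTH)

# "nonmetal" for the purpose of the covalent criterion: anything that is
# neither a d-block metal nor an alkali/alkaline-earth center
.is_nonmetal <- function(element) {
  !(element %in% c(.TRANSITION_METALS, .ALKALI, .ALKALINE_EARTH))
}
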