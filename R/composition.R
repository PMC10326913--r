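#' Elemental composition vectors
#'
#' An `element_count` is a named integer vector of atom counts (C, H, N, O, S,
#' extensible to any element with a mass-table entry). Intermediate deltas
#' (e.g. the -H2 of a disulfide) may be negative; a fully assembled species
#' must have all counts non-negative.
#'
#' @param ... Named integer counts, or a single named vector.
#' @return An object of class `element_count`.
#' @examples
#' element_count(C = 2, H = 5, N = 1, O = 2)  # glycine + water
#' @export
element_count <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    x <- args[[1]]
  } else {
    x <- unlist(args)
  }
  if (length(x) == 0L) x <- stats::setNames(numeric(0), character(0))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("element_count requires named counts", call. = FALSE)
  }
  if (any(x != round(x))) stop("element counts must be integers", call. = FALSE)
  # canonical order: known elements first, then alphabetical extras
  known <- intersect(names(.atomic_masses), names(x))
  extra <- sort(setdiff(names(x), known))
  x <- x[c(known, extra)]
  x <- x[x != 0]
  structure(as.double(x), names = names(x), class = "element_count")
}

#' @export
`+.element_count` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  element_count(out)
}

#' @export
print.element_count <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<empty composition>\n")
    return(invisible(x))
  }
  cat(paste0(names(x), ifelse(x == 1, "", x), collapse = " "),
      sprintf("(%.6f Da)\n", monoisotopic_mass(x)))
  invisible(x)
}

.scale_composition <- function(comp, n) {
  if (n == 0) return(element_count(stats::setNames(numeric(0), character(0))))
  element_count(stats::setNames(unclass(comp) * n, names(comp)))
}

.assert_assembled <- function(comp, what = "species") {
  if (any(unclass(comp) < 0)) {
    stop(sprintf("assembled composition of %s has negative element counts", what),
         call. = FALSE)
  }
  comp
}

#' Monoisotopic mass
#'
#' Sum of count times monoisotopic atomic mass over all elements of a
#' composition, or the assembled composition of a peptide / cross-linked /
#' glycopeptide species.
#'
#' @param x An `element_count`, `peptide_species`, `crosslinked_species`, or
#'   `glycan_composition`.
#' @param ... Unused.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(element_count(H = 2, O = 1))  # water, 18.010565
#' @export
monoisotopic_mass <- function(x, ...) UseMethod("monoisotopic_mass")

#' @export
monoisotopic_mass.element_count <- function(x, ...) {
  unknown <- setdiff(names(x), names(.atomic_masses))
  if (length(unknown)) {
    stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(unclass(x) * .atomic_masses[names(x)])
}

#' @export
monoisotopic_mass.default <- function(x, ...) {
  monoisotopic_mass(composition_of(x))
}
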