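#' Aggregated isotopologue pattern
#'
#' Nominal-mass (aggregated) isotopologue abundances of a composition,
#' computed by convolving per-element multinomial distributions built from
#' natural isotope abundances, truncated and renormalized to neutron offsets
#' k <= max_k. Convolution truncation is exact for the retained offsets:
#' abundances at k are unaffected by discarding higher offsets.
#'
#' @param x Composition or species.
#' @param max_k Largest neutron offset to retain (>= 0).
#' @param ... Unused.
#' @return Object of class `isotope_pattern`: data.frame with columns `k` and
#'   `abundance` (summing to 1), with attribute `argmax_k`, the most abundant
#'   offset (ties broken toward lower k).
#' @examples
#' isotope_pattern(element_count(C = 1), max_k = 3)
#' @export
isotope_pattern <- function(x, max_k = 10L, ...) UseMethod("isotope_pattern")

#' @export
isotope_pattern.element_count <- function(x, max_k = 10L, ...) {
  max_k <- as.integer(max_k)
  if (max_k < 0L) stop("max_k must be >= 0", call. = FALSE)
  if (any(unclass(x) < 0)) stop("composition has negative counts", call. = FALSE)
  unknown <- setdiff(names(x), names(.isotope_abundances))
  if (length(unknown)) {
    stop("no isotope table for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  len <- max_k + 1L
  pat <- 1
  for (el in names(x)) {
    n <- unclass(x)[[el]]
    if (n > 0) {
      pat <- .conv_trunc(pat, .dist_power(.isotope_abundances[[el]], n, len), len)
    }
  }
  ab <- numeric(len)
  ab[seq_along(pat)] <- pat
  ab <- ab / sum(ab)
  structure(data.frame(k = 0:max_k, abundance = ab),
            argmax_k = which.max(ab) - 1L,
            class = c("isotope_pattern", "data.frame"))
}

#' @export
isotope_pattern.default <- function(x, max_k = 10L, ...) {
  isotope_pattern(composition_of(x), max_k = max_k)
}

# distribution of the sum over n iid atoms, by exponentiation-by-squaring
.dist_power <- function(p, n, len) {
  out <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_trunc(out, base, len)
    n <- n %/% 2
    if (n > 0) base <- .conv_trunc(base, base, len)
  }
  out
}

.conv_trunc <- function(a, b, len) {
  out <- .poly_conv(a, b)
  out[seq_len(min(length(out), len))]
}

.poly_conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("<isotope pattern, argmax k = %d>\n", attr(x, "argmax_k")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Precursor m/z
#'
#' m/z of the isotopologue k neutrons above monoisotopic:
#' (M + k * 1.003355 + z * 1.007276) / z.
#'
#' @param species Species or composition (anything with a monoisotopic mass).
#' @param charge Number of protons (>= 1).
#' @param k Neutron offset (>= 0); 0 gives the monoisotopic peak.
#' @return m/z.
#' @examples
#' precursor_mz(peptide_species("G"), charge = 1)  # 76.0393
#' @export
precursor_mz <- function(species, charge, k = 0L) {
  if (charge < 1) stop("charge must be >= 1", call. = FALSE)
  if (k < 0) stop("neutron offset k must be >= 0", call. = FALSE)
  (monoisotopic_mass(species) + k * NEUTRON_SPACING + charge * PROTON_MASS) / charge
}

#' Fragment ion m/z
#'
#' Standard b/y fragment ions: y ions are suffix residues + water + protons,
#' b ions are prefix residues + protons; stated neutral water losses are
#' subtracted before dividing by the charge. For a cross-linked species the
#' fragment is taken from one constituent; if its residue range contains a
#' linked Cys, the full partner peptide (less 2 H per link) rides along on the
#' fragment's neutral mass.
#'
#' @param species `peptide_species` or `crosslinked_species`.
#' @param ion "b" or "y".
#' @param index Fragment index (1 to length - 1).
#' @param charge Fragment charge (>= 1).
#' @param loss_h2o Number of neutral water losses.
#' @param constituent For cross-linked species, which constituent ("a" or "b")
#'   the fragment series runs on.
#' @return m/z.
#' @examples
#' fragment_mz(peptide_species("TTPPVLDSDGSFFLYSK"), "y", 3)  # 397.21
#' @export
fragment_mz <- function(species, ion = c("b", "y"), index, charge = 1L,
                        loss_h2o = 0L, constituent = c("a", "b")) {
  ion <- match.arg(ion)
  if (charge < 1) stop("charge must be >= 1", call. = FALSE)
  if (inherits(species, "crosslinked_species")) {
    constituent <- match.arg(constituent)
    pep <- species[[constituent]]
    partner <- species[[setdiff(c("a", "b"), constituent)]]
    linked <- species$linked_cys[[constituent]]
  } else {
    pep <- species
    partner <- NULL
    linked <- integer(0)
  }
  n <- length(pep$residues)
  if (index < 1 || index >= n) {
    stop("fragment index must lie strictly inside the peptide", call. = FALSE)
  }
  range <- if (ion == "y") (n - index + 1L):n else 1L:index
  mass <- sum(vapply(pep$residues[range],
                     function(r) monoisotopic_mass(element_count(.residue_compositions[[r]])),
                     numeric(1)))
  if (ion == "y") mass <- mass + WATER_MASS
  # positioned modifications falling inside the fragment
  mods <- pep$modifications
  for (i in seq_len(nrow(mods))) {
    if (mods$position[i] %in% range) {
      mass <- mass + monoisotopic_mass(element_count(
        .builtin_modifications[[mods$name[i]]]$delta))
    }
  }
  if (!is.null(pep$glycan) && !is.na(pep$glycan_position) &&
      pep$glycan_position %in% range) {
    mass <- mass + monoisotopic_mass(composition_of(pep$glycan))
  }
  # cross-link retention: fragment keeps the whole partner peptide (-2H/link)
  if (length(linked) && any(linked %in% range)) {
    mass <- mass + monoisotopic_mass(partner) +
      species$links * monoisotopic_mass(element_count(DISULFIDE_DELTA))
  }
  loss_h2o <- as.integer(loss_h2o)
  if (loss_h2o < 0) stop("loss_h2o must be >= 0", call. = FALSE)
  mass <- mass - loss_h2o * WATER_MASS
  if (mass <= 0) stop("neutral loss not representable for this fragment", call. = FALSE)
  (mass + charge * PROTON_MASS) / charge
}

#' Glycan oxonium ion m/z
#'
#' Singly charged oxonium reporter ions used as glycoform-independent Q3
#' masses: HexNAc (204.087), its secondary fragment at nominal 138, and
#' HexNAc-Hex (366.140).
#'
#' @param ion_name One of `"HexNAc"`, `"HexNAc_frag138"`, `"HexNAc-Hex"`.
#' @return m/z of the singly charged oxonium ion.
#' @examples
#' oxonium_mz("HexNAc")
#' @export
oxonium_mz <- function(ion_name) {
  if (!ion_name %in% names(.oxonium_table)) {
    stop("unknown oxonium ion: ", ion_name, call. = FALSE)
  }
  unname(.oxonium_table[[ion_name]])
}
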