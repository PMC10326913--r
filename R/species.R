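#' N-glycan compositions
#'
#' Builds a glycan composition either from a standard IgG glycoform name
#' (Man5, G0, G0F, G1F, G2F, G1F-GN, G2FB, G1FS, G2FS, G2FS2) or from explicit
#' monomer counts. Compositions follow the usual IgG shorthand: G0 =
#' Hex3HexNAc4; F adds a core fucose (dHex); G1/G2 add galactoses (Hex); B adds
#' a bisecting HexNAc; S/S2 add sialic acids (NeuAc); G1F-GN is G1F minus one
#' antenna HexNAc.
#'
#' @param name Glycoform display name (optional if counts given).
#' @param Hex,HexNAc,dHex,NeuAc Monomer counts.
#' @return Object of class `glycan_composition`.
#' @examples
#' glycan_composition("G0F")
#' glycan_composition("custom", Hex = 3, HexNAc = 4, dHex = 1)
#' @export
glycan_composition <- function(name = NULL, Hex = NULL, HexNAc = NULL,
                               dHex = NULL, NeuAc = NULL) {
  counts <- c(Hex = Hex, HexNAc = HexNAc, dHex = dHex, NeuAc = NeuAc)
  if (is.null(counts)) {
    if (is.null(name)) stop("give a glycoform name or monomer counts", call. = FALSE)
    counts <- .glycoform_counts(name)
    if (is.null(counts)) stop("unknown glycoform name: ", name, call. = FALSE)
  }
  full <- c(Hex = 0, HexNAc = 0, dHex = 0, NeuAc = 0)
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full))) {
    stop("glycan monomer counts must be non-negative integers", call. = FALSE)
  }
  structure(list(name = if (is.null(name)) NA_character_ else name,
                 counts = full),
            class = "glycan_composition")
}

# Core IgG glycoform table (NULL for names with no defined composition).
.glycoform_counts <- function(name) {
  tbl <- list(
    "Man5"   = c(Hex = 5, HexNAc = 2),
    "G0"     = c(Hex = 3, HexNAc = 4),
    "G0F"    = c(Hex = 3, HexNAc = 4, dHex = 1),
    "G1F"    = c(Hex = 4, HexNAc = 4, dHex = 1),
    "G2F"    = c(Hex = 5, HexNAc = 4, dHex = 1),
    "G1F-GN" = c(Hex = 4, HexNAc = 3, dHex = 1),
    "G2FB"   = c(Hex = 5, HexNAc = 5, dHex = 1),
    "G1FS"   = c(Hex = 4, HexNAc = 4, dHex = 1, NeuAc = 1),
    "G2FS"   = c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 1),
    "G2FS2"  = c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 2)
  )
  tbl[[name]]
}

#' @export
composition_of.glycan_composition <- function(species, ...) {
  out <- element_count(stats::setNames(numeric(0), character(0)))
  for (m in names(species$counts)) {
    out <- out + .scale_composition(element_count(.glycan_monomers[[m]]),
                                    species$counts[[m]])
  }
  out
}

#' @export
print.glycan_composition <- function(x, ...) {
  cts <- x$counts[x$counts > 0]
  cat(sprintf("<glycan %s: %s, %.6f Da>\n",
              if (is.na(x$name)) "(unnamed)" else x$name,
              paste0(names(cts), cts, collapse = " "),
              monoisotopic_mass(composition_of(x))))
  invisible(x)
}

#' Peptide species
#'
#' A chemically defined peptide analyte: a residue sequence from a stated chain
#' interval, with positioned modifications and an optional N-glycan at a stated
#' sequon position. Modification positions must carry the residue the
#' modification attaches to (both built-ins attach to Cys).
#'
#' @param sequence One-letter residue sequence (20 standard residues).
#' @param chain Chain label, e.g. "H", "L-kappa", "L-lambda".
#' @param start,end 1-based inclusive residue interval on the chain.
#' @param modifications Named integer-position list/vector, e.g.
#'   `c(NEM = 18)`, or a data.frame with columns `name`, `position`. Repeated
#'   names allowed.
#' @param glycan A `glycan_composition` (or glycoform name) or NULL.
#' @param glycan_position Sequon position (within the peptide) of the glycan.
#' @return Object of class `peptide_species`.
#' @examples
#' peptide_species("SNFRGEC", chain = "L-kappa", start = 208, end = 214,
#'                 modifications = c(NEM = 7))
#' @export
peptide_species <- function(sequence, chain = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            modifications = NULL, glycan = NULL,
                            glycan_position = NA_integer_) {
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.residue_compositions))
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
                        call. = FALSE)
  if (!is.na(start) && !is.na(end) && (end - start + 1L) != length(residues)) {
    stop("sequence length does not match residue interval ", start, "-", end,
         call. = FALSE)
  }
  mods <- .normalize_mods(modifications)
  for (i in seq_len(nrow(mods))) {
    nm <- mods$name[i]; pos <- mods$position[i]
    def <- .builtin_modifications[[nm]]
    if (is.null(def)) stop("unknown modification: ", nm, call. = FALSE)
    if (pos < 1L || pos > length(residues)) {
      stop("modification position out of range: ", nm, "@", pos, call. = FALSE)
    }
    if (residues[pos] != def$site) {
      stop(sprintf("modification %s requires residue %s at position %d (found %s)",
                   nm, def$site, pos, residues[pos]), call. = FALSE)
    }
  }
  if (anyDuplicated(mods$position)) {
    stop("more than one modification at the same residue", call. = FALSE)
  }
  if (!is.null(glycan)) {
    if (is.character(glycan)) glycan <- glycan_composition(glycan)
    if (!is.na(glycan_position) &&
        (glycan_position < 1L || glycan_position > length(residues))) {
      stop("glycan position out of range", call. = FALSE)
    }
  }
  structure(list(sequence = sequence, residues = residues, chain = chain,
                 start = start, end = end, modifications = mods,
                 glycan = glycan, glycan_position = glycan_position),
            class = "peptide_species")
}

.normalize_mods <- function(modifications) {
  if (is.null(modifications)) {
    return(data.frame(name = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(modifications)) {
    stopifnot(all(c("name", "position") %in% names(modifications)))
    return(data.frame(name = as.character(modifications$name),
                      position = as.integer(modifications$position),
                      stringsAsFactors = FALSE))
  }
  data.frame(name = names(modifications),
             position = as.integer(modifications),
             stringsAsFactors = FALSE)
}

# Cys positions not occupied by a thiol-consuming modification.
.free_cys_positions <- function(species) {
  pos <- which(species$residues == "C")
  setdiff(pos, species$modifications$position)
}

#' Disulfide-cross-linked peptide species
#'
#' Two peptides joined by one or more interchain disulfide links. Each link
#' consumes one unmodified Cys on each constituent (assigned in sequence
#' order) and removes 2 H (2.015650 Da) from the summed composition.
#'
#' @param a,b Constituent `peptide_species`.
#' @param links Number of interchain disulfide links (>= 1).
#' @return Object of class `crosslinked_species`.
#' @examples
#' lam <- peptide_species("TVAPTECS")
#' hng <- peptide_species("SCDK")
#' crosslinked_species(lam, hng, links = 1)
#' @export
crosslinked_species <- function(a, b, links = 1L) {
  stopifnot(inherits(a, "peptide_species"), inherits(b, "peptide_species"))
  links <- as.integer(links)
  if (links < 1L) stop("links must be >= 1", call. = FALSE)
  for (sp in list(a, b)) {
    if (length(.free_cys_positions(sp)) < links) {
      stop("more disulfide links than available unmodified Cys", call. = FALSE)
    }
  }
  structure(list(a = a, b = b, links = links,
                 linked_cys = list(a = .free_cys_positions(a)[seq_len(links)],
                                   b = .free_cys_positions(b)[seq_len(links)])),
            class = "crosslinked_species")
}

#' Elemental composition of a species
#'
#' Assembles the full elemental composition: residue compositions plus one
#' water per constituent chain, plus modification deltas and glycan monomers,
#' minus 2 H per disulfide link.
#'
#' @param species A `peptide_species`, `crosslinked_species`,
#'   `glycan_composition`, or bare sequence string.
#' @param ... Unused.
#' @return An `element_count` with all counts non-negative.
#' @examples
#' composition_of("G")  # C2H5NO2
#' @export
composition_of <- function(species, ...) UseMethod("composition_of")

#' @export
composition_of.character <- function(species, ...) {
  composition_of(peptide_species(species))
}

#' @export
composition_of.peptide_species <- function(species, ...) {
  out <- element_count(H = 2, O = 1)  # chain water
  for (r in species$residues) out <- out + element_count(.residue_compositions[[r]])
  for (i in seq_len(nrow(species$modifications))) {
    out <- out + element_count(.builtin_modifications[[species$modifications$name[i]]]$delta)
  }
  if (!is.null(species$glycan)) out <- out + composition_of(species$glycan)
  .assert_assembled(out, species$sequence)
}

#' @export
composition_of.crosslinked_species <- function(species, ...) {
  out <- composition_of(species$a) + composition_of(species$b) +
    .scale_composition(element_count(DISULFIDE_DELTA), species$links)
  .assert_assembled(out, "crosslinked species")
}

#' @export
print.peptide_species <- function(x, ...) {
  loc <- if (!is.na(x$start)) sprintf(" %s%d-%d", x$chain, x$start, x$end) else ""
  mods <- if (nrow(x$modifications)) {
    paste0(" +", paste0(x$modifications$name, "@", x$modifications$position,
                        collapse = ",+"))
  } else ""
  gly <- if (!is.null(x$glycan)) paste0(" +", x$glycan$name) else ""
  cat(sprintf("<peptide%s %s%s%s, %.5f Da>\n", loc, x$sequence, mods, gly,
              monoisotopic_mass(x)))
  invisible(x)
}

#' @export
print.crosslinked_species <- function(x, ...) {
  cat(sprintf("<crosslinked %s x %s, %d S-S link(s), %.5f Da>\n",
              x$a$sequence, x$b$sequence, x$links, monoisotopic_mass(x)))
  invisible(x)
}
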