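# The transition panel: the four attribute blocks (thiol state of the
# inserted cysteine, Fc glycosylation, interchain-disulfide partial reduction,
# polypeptide fragmentation) monitored on a triple quadrupole after
# NEM capping and Lys-C digestion. Q1/Q3 values stored in the panel are the
# instrument-tuned empirical values; the chemically computed m/z of each
# species is advisory and used only by validate_panel().

.HINGE_SEQ <- "THTCPPCPAPELLGGPSCVFLFPPKPK"      # H222-H248; inserted Cys at 18 (C239)
.GLYCOPEP_SEQ <- "TKPREEQYNSTYRVVSVLTVLHQDWLNGK" # H289-H317; sequon Asn at 9 (N297)
.STD_SEQ <- "TTPPVLDSDGSFFLYSK"                  # conserved CH3 standard, H393-H409

.hinge_monomer <- function(modifications = NULL) {
  peptide_species(.HINGE_SEQ, chain = "H", start = 222L, end = 248L,
                  modifications = modifications)
}

# Species registry: species_id -> chemically defined analyte (or NULL for
# panel compounds carried with empirical Q1 only).
#' Resolve a panel species identifier
#'
#' Returns the chemically defined species behind a panel `species_id`, from
#' which computed m/z values derive. `"H289-H317+G1F-GN+NAc"` has no defined
#' composition and returns NULL (its Q1 is empirical only).
#'
#' @param species_id Identifier as used in the transition table.
#' @return A species object, or NULL when no composition is defined.
#' @export
panel_species <- function(species_id) {
  glyco <- function(name) {
    peptide_species(.GLYCOPEP_SEQ, chain = "H", start = 289L, end = 317L,
                    glycan = name, glycan_position = 9L)
  }
  thiol_dimer <- function(mods_per_chain, links) {
    crosslinked_species(.hinge_monomer(mods_per_chain[[1]]),
                        .hinge_monomer(mods_per_chain[[2]]), links = links)
  }
  switch(species_id,
    # fragmentation peptides
    "H310-H317" = peptide_species("HQDWLNGK", "H", 310L, 317L),
    "H278-H288" = peptide_species("YVDGVEVHNAK", "H", 278L, 288L),
    "H307-H317" = peptide_species("TVLHQDWLNGK", "H", 307L, 317L),
    "H277-H288" = peptide_species("WYVDGVEVHNAK", "H", 277L, 288L),
    "H275-H288" = peptide_species("FNWYVDGVEVHNAK", "H", 275L, 288L),
    "H393-H409" = peptide_species(.STD_SEQ, "H", 393L, 409L),
    # partial-reduction peptides (reduced forms are NEM-capped)
    "lambda-linked" = crosslinked_species(
      peptide_species("TVAPTECS", "L-lambda", 209L, 216L),
      peptide_species("SCDK", "H", 218L, 221L), links = 1L),
    "kappa-linked" = crosslinked_species(
      peptide_species("SNFRGEC", "L-kappa", 208L, 214L),
      peptide_species("SCDK", "H", 223L, 226L), links = 1L),
    "lambda-reduced" = peptide_species("TVAPTECS", "L-lambda", 209L, 216L,
                                       modifications = c(NEM = 7L)),
    "kappa-reduced" = peptide_species("SNFRGEC", "L-kappa", 208L, 214L,
                                      modifications = c(NEM = 7L)),
    "heavy-reduced" = .hinge_monomer(c(NEM = 4L, NEM = 7L, NEM = 18L)),
    # glycopeptides
    "H289-H317+Man5"   = glyco("Man5"),
    "H289-H317+G0"     = glyco("G0"),
    "H289-H317+G0F"    = glyco("G0F"),
    "H289-H317+G1F"    = glyco("G1F"),
    "H289-H317+G2F"    = glyco("G2F"),
    "H289-H317+G1F-GN" = glyco("G1F-GN"),
    "H289-H317+G2FB"   = glyco("G2FB"),
    "H289-H317+G1FS"   = glyco("G1FS"),
    "H289-H317+G2FS"   = glyco("G2FS"),
    "H289-H317+G2FS2"  = glyco("G2FS2"),
    "H289-H317+G1F-GN+NAc" = NULL,  # ambiguous composition; empirical Q1 only
    # hinge-dimer thiol states (two canonical hinge S-S links; inserted Cys
    # at position 18 carries NEM / cysteinylation / the extra iDSB link)
    "hinge-dimer-2xSH"  = thiol_dimer(list(c(NEM = 18L), c(NEM = 18L)), 2L),
    "hinge-dimer-1xSH1xCys" = thiol_dimer(list(c(NEM = 18L),
                                               c(cysteinylation = 18L)), 2L),
    "hinge-dimer-2xCys" = thiol_dimer(list(c(cysteinylation = 18L),
                                           c(cysteinylation = 18L)), 2L),
    "hinge-dimer-iDSB"  = thiol_dimer(list(NULL, NULL), 3L),
    stop("unknown species_id: ", species_id, call. = FALSE)
  )
}

.panel_columns <- c("attribute_class", "compound_id", "species_id",
                    "precursor_charge", "q1_mz", "q3_mz", "fragment_label",
                    "rt_start_min", "rt_end_min", "role")

#' Build the default transition panel
#'
#' The full 36-transition panel: 12 fragmentation, 9 partial-reduction,
#' 11 glycosylation and 4 thiol-state transitions, with the empirical
#' (instrument-tuned) Q1/Q3 values and retention-time windows, plus the
#' species definition behind each compound. Compound ids are
#' `"<analyte>.<fragment label>"`; transitions of the same analyte are summed
#' at quantitation time.
#'
#' @param isotype Light-chain isotype carried by the panel: "both" keeps the
#'   kappa and lambda partial-reduction transitions side by side.
#' @return An `attribute_panel` (data.frame of transitions with an `isotype`
#'   attribute).
#' @examples
#' panel <- build_default_panel()
#' table(panel$attribute_class)
#' @export
build_default_panel <- function(isotype = c("both", "kappa", "lambda")) {
  isotype <- match.arg(isotype)
  tr <- function(class, analyte, species, z, q1, q3, frag, rt1, rt2, role) {
    data.frame(attribute_class = class,
               compound_id = paste0(analyte, ".", frag),
               species_id = species, precursor_charge = z,
               q1_mz = q1, q3_mz = q3, fragment_label = frag,
               rt_start_min = rt1, rt_end_min = rt2, role = role,
               stringsAsFactors = FALSE)
  }
  fr <- "fragmentation"; pr <- "partial_reduction"
  gl <- "glycosylation"; th <- "thiol_state"
  rows <- list(
    tr(fr, "Frag1", "H310-H317", 2L, 499.20, 204.12, "y2", 4.00, 4.80, "analyte"),
    tr(fr, "Frag1", "H310-H317", 2L, 499.20, 318.16, "y3", 4.00, 4.80, "analyte"),
    tr(fr, "Frag2", "H278-H288", 2L, 615.80, 469.20, "y4", 3.80, 4.40, "analyte"),
    tr(fr, "Frag2", "H278-H288", 2L, 615.80, 968.40, "y9", 3.80, 4.40, "analyte"),
    tr(fr, "Frag3", "H307-H317", 2L, 655.82, 204.12, "y2", 4.40, 4.80, "analyte"),
    tr(fr, "Frag3", "H307-H317", 2L, 655.82, 318.16, "y3", 4.40, 4.80, "analyte"),
    tr(fr, "Frag4", "H277-H288", 2L, 708.80, 469.20, "y4", 4.30, 5.10, "analyte"),
    tr(fr, "Frag4", "H277-H288", 2L, 708.80, 968.40, "y9", 4.30, 5.10, "analyte"),
    tr(fr, "wildtype", "H275-H288", 2L, 839.35, 469.20, "y4", 4.60, 5.30, "parent"),
    tr(fr, "wildtype", "H275-H288", 2L, 839.35, 968.40, "y9", 4.60, 5.30, "parent"),
    tr(fr, "standard", "H393-H409", 2L, 937.46, 397.21, "y3", 5.10, 5.60, "standard"),
    tr(fr, "standard", "H393-H409", 2L, 937.46, 836.43, "y15", 5.10, 5.60, "standard"),
    tr(pr, "lambda_linked", "lambda-linked", 2L, 628.76, 484.20, "y5-H2O", 3.60, 4.40, "parent"),
    tr(pr, "lambda_linked", "lambda-linked", 2L, 628.76, 658.20, "y2", 3.60, 4.40, "parent"),
    tr(pr, "kappa_linked", "kappa-linked", 2L, 631.25, 562.30, "b5", 3.50, 4.50, "parent"),
    tr(pr, "lambda_reduced", "lambda-reduced", 1L, 932.45, 661.30, "y5", 4.20, 4.75, "analyte"),
    tr(pr, "lambda_reduced", "lambda-reduced", 1L, 932.45, 732.40, "y6", 4.20, 4.75, "analyte"),
    tr(pr, "kappa_reduced", "kappa-reduced", 1L, 937.38, 505.30, "b4", 4.00, 4.60, "analyte"),
    tr(pr, "kappa_reduced", "kappa-reduced", 1L, 937.38, 562.30, "b5", 4.00, 4.60, "analyte"),
    tr(pr, "heavy_reduced", "heavy-reduced", 3L, 1070.58, 1321.80, "y23", 5.50, 7.50, "analyte"),
    tr(pr, "heavy_reduced", "heavy-reduced", 3L, 1070.58, 1435.85, "y24", 5.50, 7.50, "analyte"),
    tr(gl, "Man5", "H289-H317+Man5", 4L, 1170.34, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G0", "H289-H317+G0", 4L, 1191.07, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G1F-GN", "H289-H317+G1F-GN", 4L, 1216.83, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G0F", "H289-H317+G0F", 4L, 1227.59, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G1F", "H289-H317+G1F", 4L, 1268.10, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G1F-GN+NAc", "H289-H317+G1F-GN+NAc", 4L, 1291.40, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G2F", "H289-H317+G2F", 4L, 1308.60, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G1FS", "H289-H317+G1FS", 4L, 1340.80, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G2FB", "H289-H317+G2FB", 4L, 1358.88, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G2FS", "H289-H317+G2FS", 4L, 1381.60, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(gl, "G2FS2", "H289-H317+G2FS2", 4L, 1454.41, 138.00, "oxonium138", 4.80, 5.50, "analyte"),
    tr(th, "iDSB", "hinge-dimer-iDSB", 4L, 1416.50, 566.30, "y5", 5.10, 7.50, "analyte"),
    tr(th, "2xCys", "hinge-dimer-2xCys", 4L, 1476.70, 566.30, "y5", 5.10, 7.50, "analyte"),
    tr(th, "1xSH1xCys", "hinge-dimer-1xSH1xCys", 4L, 1478.20, 566.30, "y5", 5.10, 7.50, "analyte"),
    tr(th, "2xSH", "hinge-dimer-2xSH", 4L, 1479.70, 566.30, "y5", 5.10, 7.50, "analyte")
  )
  panel <- do.call(rbind, rows)
  if (isotype == "kappa") panel <- panel[!grepl("^lambda_", panel$compound_id), ]
  if (isotype == "lambda") panel <- panel[!grepl("^kappa_", panel$compound_id), ]
  rownames(panel) <- NULL
  structure(panel, isotype = isotype, class = c("attribute_panel", "data.frame"))
}

#' Analyte label of panel compounds
#'
#' Compound ids are `"<analyte>.<fragment label>"`; this strips the fragment
#' suffix so transitions of the same analyte can be grouped.
#'
#' @param compound_id Character vector of compound ids.
#' @return Analyte labels.
#' @export
panel_analyte <- function(compound_id) {
  sub("\\.[^.]*$", "", compound_id)
}

.sialylated_glycoforms <- c("G1FS", "G2FS", "G2FS2", "G1F-GN+NAc")

.check_panel_structure <- function(panel) {
  missing_cols <- setdiff(.panel_columns, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  msgs <- character(0)
  if (anyDuplicated(panel$compound_id)) {
    msgs <- c(msgs, paste("duplicate compound ids:",
                          paste(unique(panel$compound_id[duplicated(panel$compound_id)]),
                                collapse = ", ")))
  }
  if (any(panel$rt_start_min >= panel$rt_end_min)) {
    msgs <- c(msgs, "retention-time window with start >= end")
  }
  if (any(panel$q1_mz <= 0) || any(panel$q3_mz <= 0)) {
    msgs <- c(msgs, "non-positive Q1 or Q3 m/z")
  }
  for (cls in unique(panel$attribute_class)) {
    n_analytes <- length(unique(panel_analyte(panel$compound_id[panel$attribute_class == cls])))
    if (n_analytes < 2) {
      msgs <- c(msgs, paste0("attribute class '", cls,
                             "' has fewer than 2 compounds; a proportion needs a denominator"))
    }
  }
  frg <- panel[panel$attribute_class == "fragmentation", ]
  if (nrow(frg)) {
    analytes <- unique(panel_analyte(frg$compound_id[frg$role == "analyte"]))
    if (length(analytes) &&
        !any(frg$role %in% c("parent", "standard"))) {
      msgs <- c(msgs, "fragmentation analytes lack a parent or standard compound")
    }
  }
  msgs
}

#' Validate a transition panel
#'
#' Checks structure (unique compound ids, sane windows, denominators present),
#' compares stored empirical Q1 against the computed isotopologue envelope of
#' each defined species, and flags compound pairs that are too close in both
#' Q1 and Q3 with overlapping retention windows ("needs chromatographic
#' separation" -- codetection on a unit-resolution quadrupole can only be
#' avoided by the LC gradient).
#'
#' @param panel An `attribute_panel`.
#' @param q1_tol,q3_tol Cross-talk tolerances in m/z. Defaults 2.0 / 0.7
#'   reflect a unit-resolution quad plus the width of a 4+ isotope envelope.
#' @param q1_max_dev Maximum tolerated |computed - stored| Q1 deviation over
#'   isotopologues k = 0..5.
#' @return data.frame of findings (`type`, `severity`, `compounds`, `detail`);
#'   zero rows means a clean panel.
#' @export
validate_panel <- function(panel, q1_tol = 2.0, q3_tol = 0.7, q1_max_dev = 0.5) {
  if (q1_tol <= 0 || q3_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  finding <- function(type, severity, compounds, detail) {
    data.frame(type = type, severity = severity, compounds = compounds,
               detail = detail, stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in .check_panel_structure(panel)) {
    out[[length(out) + 1L]] <- finding("structure", "failure", "", m)
  }
  # computed-vs-stored Q1 (per analyte, empirical Q1 identical across its rows)
  first_rows <- panel[!duplicated(panel_analyte(panel$compound_id)), ]
  for (i in seq_len(nrow(first_rows))) {
    sp <- tryCatch(panel_species(first_rows$species_id[i]), error = function(e) NULL)
    if (is.null(sp)) next
    z <- first_rows$precursor_charge[i]
    mzs <- vapply(0:5, function(k) precursor_mz(sp, z, k), numeric(1))
    dev <- min(abs(mzs - first_rows$q1_mz[i]))
    if (dev > q1_max_dev) {
      out[[length(out) + 1L]] <- finding(
        "q1_deviation", "warning", first_rows$compound_id[i],
        sprintf("stored Q1 %.2f is %.2f m/z from nearest computed isotopologue",
                first_rows$q1_mz[i], dev))
    }
  }
  # pairwise cross-talk
  n <- nrow(panel)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (panel_analyte(panel$compound_id[i]) == panel_analyte(panel$compound_id[j])) next
      close_mz <- abs(panel$q1_mz[i] - panel$q1_mz[j]) < q1_tol &&
        abs(panel$q3_mz[i] - panel$q3_mz[j]) < q3_tol
      overlap <- panel$rt_start_min[i] < panel$rt_end_min[j] &&
        panel$rt_start_min[j] < panel$rt_end_min[i]
      if (close_mz && overlap) {
        sev <- if (panel$q1_mz[i] == panel$q1_mz[j] &&
                   panel$q3_mz[i] == panel$q3_mz[j]) "failure" else "warning"
        out[[length(out) + 1L]] <- finding(
          "cross_talk", sev,
          paste(panel$compound_id[i], panel$compound_id[j], sep = " / "),
          "needs chromatographic separation")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), severity = character(0),
                      compounds = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read / write a transition panel CSV
#'
#' Comma-separated UTF-8 with header columns `attribute_class, compound_id,
#' species_id, precursor_charge, q1_mz, q3_mz, fragment_label, rt_start_min,
#' rt_end_min, role`. `write_transitions()` followed by `read_transitions()`
#' is the identity on valid panels.
#'
#' @param path File path.
#' @param isotype Isotype attribute to attach on read.
#' @return `read_transitions()` returns an `attribute_panel`.
#' @export
read_transitions <- function(path, isotype = "both") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.panel_columns, names(raw))
  if (length(missing_cols)) {
    stop("transition file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), .panel_columns)
  if (length(extra)) {
    stop("transition file has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("unparseable %s value '%s' at row %d", col, raw[[col]][bad[1]],
                   bad[1]), call. = FALSE)
    }
    v
  }
  panel <- data.frame(attribute_class = raw$attribute_class,
                      compound_id = raw$compound_id,
                      species_id = raw$species_id,
                      precursor_charge = as.integer(num("precursor_charge")),
                      q1_mz = num("q1_mz"), q3_mz = num("q3_mz"),
                      fragment_label = raw$fragment_label,
                      rt_start_min = num("rt_start_min"),
                      rt_end_min = num("rt_end_min"),
                      role = raw$role, stringsAsFactors = FALSE)
  if (anyDuplicated(panel$compound_id)) {
    stop("duplicate compound ids in transition file", call. = FALSE)
  }
  structure(panel, isotype = isotype, class = c("attribute_panel", "data.frame"))
}

#' @rdname read_transitions
#' @param panel Panel to serialize.
#' @export
write_transitions <- function(panel, path) {
  df <- as.data.frame(panel)[, .panel_columns]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.attribute_panel <- function(x, ...) {
  cat(sprintf("<attribute panel: %d transitions, %d analytes, isotype %s>\n",
              nrow(x), length(unique(panel_analyte(x$compound_id))),
              attr(x, "isotype") %||% "both"))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
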