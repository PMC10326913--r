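# Relative quantitation of the four attributes from MRM peak areas.
# All four statistics are ratios of (corrected) areas, so they are invariant
# to the overall abundance scale of a sample:
#   thiol state:        %_i = 100 * corrected_i / sum over the four states
#   partial reduction:  %_bond = 100 * reduced / (reduced + linked)
#   glycoforms:         %_g = 100 * corrected_g / sum over glycoforms
#   fragmentation:      vs-parent  %_s = 100 * frag / (frag + parent)
#                       vs-standard ratio = 100 * frag / standard

#' Correction model
#'
#' Per-analyte multiplicative corrections with provenance. Blend-derived
#' response `factors` DIVIDE the raw area (they encode how strongly an analyte
#' ionizes relative to the reference); orthogonal-bridge glycan `conversions`
#' MULTIPLY the raw area before renormalization. Unnamed analytes default to
#' 1 in both directions.
#'
#' @param factors Named response factors (> 0); reference compound has 1.
#' @param conversions Named per-glycoform conversion factors (> 0).
#' @param provenance One of "blend-fit", "equimolar-mix", "orthogonal-bridge",
#'   "none".
#' @return Object of class `correction_model`.
#' @export
correction_model <- function(factors = NULL, conversions = NULL,
                             provenance = c("none", "blend-fit",
                                            "equimolar-mix",
                                            "orthogonal-bridge")) {
  provenance <- match.arg(provenance)
  for (v in list(factors, conversions)) {
    if (!is.null(v) && (any(!is.finite(v)) || any(v <= 0))) {
      stop("correction factors must be finite and > 0", call. = FALSE)
    }
  }
  structure(list(factors = factors, conversions = conversions,
                 provenance = provenance),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction model (%s)>\n", x$provenance))
  if (!is.null(x$factors)) {
    cat("  response factors (divide):\n")
    for (n in names(x$factors)) cat(sprintf("    %-14s %.4f\n", n, x$factors[[n]]))
  }
  if (!is.null(x$conversions)) {
    cat("  conversion factors (multiply):\n")
    for (n in names(x$conversions)) cat(sprintf("    %-14s %.4f\n", n, x$conversions[[n]]))
  }
  invisible(x)
}

#' Serialize / load a correction model as YAML
#'
#' @param model A `correction_model`.
#' @param path File path.
#' @export
write_correction_model <- function(model, path) {
  yaml::write_yaml(list(provenance = model$provenance,
                        factors = as.list(model$factors),
                        conversions = as.list(model$conversions)), path)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  obj <- yaml::read_yaml(path)
  correction_model(factors = if (length(obj$factors)) unlist(obj$factors),
                   conversions = if (length(obj$conversions)) unlist(obj$conversions),
                   provenance = obj$provenance %||% "none")
}

.factor_of <- function(correction, analyte) {
  if (is.null(correction) || is.null(correction$factors)) return(1)
  if (analyte %in% names(correction$factors)) correction$factors[[analyte]] else 1
}

.conversion_of <- function(correction, analyte) {
  if (is.null(correction) || is.null(correction$conversions)) return(1)
  if (analyte %in% names(correction$conversions)) correction$conversions[[analyte]] else 1
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of `max(intensity - baseline, 0)` over the window,
#' with the baseline linearly interpolated between the medians of the first
#' and last few points inside the window (switch off with `baseline = FALSE`).
#' An empty or all-zero trace yields area 0 with a `no_peak` flag.
#'
#' @param trace data.frame with columns `time_min`, `intensity`, time-sorted.
#' @param window `c(start, end)` minutes; NULL integrates the whole trace.
#' @param baseline Subtract an edge-interpolated baseline first?
#' @param edge_points Number of window-edge points defining the baseline.
#' @return list(area =, flag = "ok" | "no_peak").
#' @export
integrate_peak <- function(trace, window = NULL, baseline = TRUE,
                           edge_points = 3L) {
  stopifnot(all(c("time_min", "intensity") %in% names(trace)))
  tt <- trace$time_min
  if (is.unsorted(tt, strictly = FALSE)) stop("trace is not time-sorted", call. = FALSE)
  if (!is.null(window)) {
    if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9) {
      stop("integration window outside the trace span", call. = FALSE)
    }
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]
    y <- trace$intensity[keep]
  } else {
    y <- trace$intensity
  }
  if (length(tt) < 2L || all(y == 0)) return(list(area = 0, flag = "no_peak"))
  if (baseline) {
    k <- min(edge_points, length(y))
    b1 <- stats::median(utils::head(y, k))
    b2 <- stats::median(utils::tail(y, k))
    bl <- b1 + (b2 - b1) * (tt - tt[1]) / (tt[length(tt)] - tt[1])
    y <- pmax(y - bl, 0)
  }
  area <- sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(area = area, flag = if (area > 0) "ok" else "no_peak")
}

#' Thiol-state percentages
#'
#' Each state's corrected signal (area divided by its response factor) as a
#' percentage of the summed corrected signal across all states.
#'
#' @param areas Named areas over the four thiol states.
#' @param correction Optional `correction_model`.
#' @return Named percentages summing to 100.
#' @examples
#' thiol_percentages(c(`2xSH` = 1, `1xSH1xCys` = 1, `2xCys` = 1, iDSB = 1))
#' @export
thiol_percentages <- function(areas, correction = NULL) {
  missing_states <- setdiff(.THIOL_STATES, names(areas))
  if (length(missing_states)) {
    stop("missing thiol-state compound(s): ", paste(missing_states, collapse = ", "),
         call. = FALSE)
  }
  a <- areas[.THIOL_STATES]
  if (all(a == 0)) stop("no signal in any thiol state", call. = FALSE)
  corr <- vapply(.THIOL_STATES, function(s) a[[s]] / .factor_of(correction, s),
                 numeric(1))
  100 * corr / sum(corr)
}

#' Partial-reduction percentages per bond
#'
#' Per bond, 100 * corrected reduced / (corrected reduced + corrected linked).
#' The heavy-light bond uses the kappa or lambda C-terminal peptides (isotype
#' auto-selected from whichever linked compound carries signal); the
#' heavy-heavy bond uses the reduced hinge peptide against the summed signal
#' of the four hinge-dimer thiol states.
#'
#' @param areas Named analyte areas (linked/reduced compounds and the four
#'   thiol states).
#' @param correction Optional `correction_model`.
#' @param isotype "auto", "kappa" or "lambda".
#' @return Named percentages `c(heavy_light =, heavy_heavy =)` with an
#'   `isotype` attribute.
#' @export
reduction_percentages <- function(areas, correction = NULL,
                                  isotype = c("auto", "kappa", "lambda")) {
  isotype <- match.arg(isotype)
  if (isotype == "auto") {
    lam <- if ("lambda_linked" %in% names(areas)) areas[["lambda_linked"]] else 0
    kap <- if ("kappa_linked" %in% names(areas)) areas[["kappa_linked"]] else 0
    if (lam == 0 && kap == 0) {
      stop("no signal in either isotype's linked compound; specify isotype",
           call. = FALSE)
    }
    isotype <- if (lam >= kap) "lambda" else "kappa"
  }
  need <- c(paste0(isotype, c("_linked", "_reduced")), .THIOL_STATES,
            "heavy_reduced")
  missing_cmp <- setdiff(need, names(areas))
  if (length(missing_cmp)) {
    stop("missing compound(s): ", paste(missing_cmp, collapse = ", "),
         call. = FALSE)
  }
  cv <- function(a) areas[[a]] / .factor_of(correction, a)
  red_hl <- cv(paste0(isotype, "_reduced"))
  lnk_hl <- cv(paste0(isotype, "_linked"))
  red_hh <- cv("heavy_reduced")
  lnk_hh <- sum(vapply(.THIOL_STATES, cv, numeric(1)))
  pct <- function(red, lnk) {
    if (red + lnk == 0) return(0)
    100 * red / (red + lnk)
  }
  structure(c(heavy_light = pct(red_hl, lnk_hl),
              heavy_heavy = pct(red_hh, lnk_hh)),
            isotype = isotype)
}

#' Glycoform percentages
#'
#' Conversion-corrected glycoform areas renormalized to 100, plus the total
#' sialylated percentage (G1FS, G2FS, G2FS2, G1F-GN+NAc).
#'
#' @param areas Named areas over glycoform analytes.
#' @param correction Optional `correction_model` (uses its `conversions`).
#' @return Named percentages with a `sialylated` attribute.
#' @export
glyco_percentages <- function(areas, correction = NULL) {
  if (!length(areas) || all(areas == 0)) {
    stop("no signal in any glycoform", call. = FALSE)
  }
  corr <- vapply(names(areas),
                 function(g) areas[[g]] * .conversion_of(correction, g),
                 numeric(1))
  pct <- 100 * corr / sum(corr)
  structure(pct,
            sialylated = sum(pct[intersect(names(pct), .sialylated_glycoforms)]))
}

#' Fragmentation percentages per site
#'
#' Sites with a resolvable unfragmented parent are reported as
#' 100 * frag / (frag + parent) ("vs-parent"). Sites on a peptide carrying
#' several fragmentation sites are reported relative to the conserved CH3
#' standard peptide as 100 * frag / standard ("vs-standard"); that ratio is
#' not bounded by 100 and is flagged accordingly.
#'
#' @param areas Named analyte areas (`Frag1..Frag4`, `wildtype`, `standard`).
#' @param correction Optional `correction_model`.
#' @return data.frame `analyte`, `value_percent`, `mode`.
#' @export
fragmentation_percentages <- function(areas, correction = NULL) {
  cv <- function(a) {
    if (!a %in% names(areas)) return(NA_real_)
    areas[[a]] / .factor_of(correction, a)
  }
  modes <- c(Frag1 = "vs-standard", Frag2 = "vs-parent",
             Frag3 = "vs-standard", Frag4 = "vs-parent")
  sites <- intersect(names(modes), names(areas))
  vals <- numeric(0)
  used_modes <- character(0)
  for (s in sites) {
    fragv <- cv(s)
    if (modes[[s]] == "vs-parent") {
      parent <- cv("wildtype")
      if (is.na(parent)) stop("parent compound 'wildtype' absent", call. = FALSE)
      v <- if (fragv + parent == 0) 0 else 100 * fragv / (fragv + parent)
    } else {
      std <- cv("standard")
      if (is.na(std) || std == 0) {
        stop("standard compound absent or zero; vs-standard ratio undefined",
             call. = FALSE)
      }
      v <- 100 * fragv / std
    }
    vals <- c(vals, v)
    used_modes <- c(used_modes, modes[[s]])
  }
  data.frame(analyte = sites, value_percent = vals, mode = used_modes,
             stringsAsFactors = FALSE)
}

# Sum transition areas per analyte for one sample.
.analyte_areas <- function(peaks, panel) {
  known <- setdiff(unique(peaks$compound_id), panel$compound_id)
  if (length(known)) {
    stop("peak table references compound(s) not in the panel: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  cls <- stats::setNames(panel$attribute_class, panel$compound_id)
  an <- panel_analyte(peaks$compound_id)
  tapply_sum <- tapply(peaks$area, an, sum)
  list(areas = stats::setNames(as.numeric(tapply_sum), names(tapply_sum)),
       class_of = stats::setNames(cls[peaks$compound_id],
                                  panel_analyte(peaks$compound_id)))
}

#' Quantify the four attributes from a peak table
#'
#' Sums transition areas per analyte, then applies the four relative
#' quantitation statistics sample by sample.
#'
#' @param peaks Peak table (`sample_id, compound_id, rt_min, area`).
#' @param panel The `attribute_panel` the peaks were acquired against.
#' @param correction Optional `correction_model`.
#' @param isotype Light-chain isotype for partial reduction ("auto" picks the
#'   isotype whose linked compound carries signal).
#' @return An `attribute_report`: tidy data.frame `sample_id,
#'   attribute_class, analyte, value_percent, mode, flags`.
#' @export
quantify_attributes <- function(peaks, panel = build_default_panel(),
                                correction = NULL,
                                isotype = c("auto", "kappa", "lambda")) {
  isotype <- match.arg(isotype)
  need <- c("sample_id", "compound_id", "area")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols)) {
    stop("peak table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(peaks)) stop("no samples in peak table", call. = FALSE)
  if (any(!is.finite(peaks$area)) || any(peaks$area < 0)) {
    stop("areas must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(peaks[c("sample_id", "compound_id")])) {
    stop("duplicate (sample, compound) rows in peak table", call. = FALSE)
  }
  out <- list()
  for (s in unique(peaks$sample_id)) {
    sub <- peaks[peaks$sample_id == s, ]
    aa <- .analyte_areas(sub, panel)
    areas <- aa$areas
    row <- function(class, analyte, value, mode, flag = "") {
      data.frame(sample_id = s, attribute_class = class, analyte = analyte,
                 value_percent = as.numeric(value), mode = mode, flags = flag,
                 stringsAsFactors = FALSE)
    }
    th <- thiol_percentages(areas, correction)
    out[[length(out) + 1L]] <- row("thiol_state", names(th), th,
                                   "percent-of-states")
    gly_analytes <- intersect(unique(panel_analyte(
      panel$compound_id[panel$attribute_class == "glycosylation"])), names(areas))
    gl <- glyco_percentages(areas[gly_analytes], correction)
    out[[length(out) + 1L]] <- row("glycosylation", names(gl), as.numeric(gl),
                                   "percent-of-glycoforms")
    out[[length(out) + 1L]] <- row("glycosylation", "sialylated",
                                   attr(gl, "sialylated"),
                                   "percent-of-glycoforms")
    rd <- reduction_percentages(areas, correction, isotype)
    out[[length(out) + 1L]] <- row("partial_reduction", names(rd),
                                   as.numeric(rd), "percent-reduced",
                                   paste0("isotype=", attr(rd, "isotype")))
    fr <- fragmentation_percentages(areas, correction)
    out[[length(out) + 1L]] <- row("fragmentation", fr$analyte,
                                   fr$value_percent, fr$mode,
                                   ifelse(fr$mode == "vs-standard",
                                          "unbounded-ratio", ""))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("attribute_report", "data.frame"))
}

#' @export
print.attribute_report <- function(x, ...) {
  cat(sprintf("<attribute report: %d sample(s)>\n", length(unique(x$sample_id))))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Peak-table and report serialization
#'
#' Peak tables are CSV with columns `sample_id, compound_id, rt_min, area`;
#' chromatograms are long CSV `sample_id, compound_id, time_min, intensity`;
#' reports are written as tidy CSV or JSON.
#'
#' @param path File path.
#' @return `read_peak_table()` returns the peak-table data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound_id", "rt_min", "area")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peak table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_peak_table
#' @param peaks Peak table.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname read_peak_table
#' @param report An `attribute_report`.
#' @param format "csv" or "json".
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
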