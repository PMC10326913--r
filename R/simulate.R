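# Synthetic MRM data generator. Ground truth holds the true attribute
# proportions of one sample; the instrument model holds per-analyte response
# factors (relative ionization propensity), optional second-order bias, the
# multiplicative noise CV, chromatographic peak shape, and the in-source
# fragmentation model. Expected areas are closed-form, so every downstream
# quantitation stage has an exact oracle.

.THIOL_STATES <- c("2xSH", "1xSH1xCys", "2xCys", "iDSB")
.GLYCOFORMS <- c("Man5", "G0", "G1F-GN", "G0F", "G1F", "G1F-GN+NAc",
                 "G2F", "G1FS", "G2FB", "G2FS", "G2FS2")
.FRAG_SITES <- c("Frag1", "Frag2", "Frag3", "Frag4")

#' Ground-truth attribute state of a simulated sample
#'
#' Default proportions emulate the process-development samples the method was
#' built for: exclusively oxidized thiol states with roughly a fifth of the
#' molecules carrying the extra interchain disulfide (iDSB), a complex
#' biantennary Fc glycan profile with ~20 % sialylated species, low single-digit
#' partial reduction and percent-level site fragmentation.
#'
#' @param thiol Named proportions over `2xSH, 1xSH1xCys, 2xCys, iDSB` (sum 1).
#' @param glyco Named proportions over the panel glycoforms (sum 1).
#' @param reduction Per-bond reduced fractions, `c(heavy_light=, heavy_heavy=)`,
#'   each in `[0, 1]`.
#' @param fragmentation Per-site fragmented fractions (`Frag1..Frag4`) in
#'   `[0, 1]`; sites 2 and 4 share the wildtype parent peptide, so their sum
#'   must stay below 1.
#' @param abundance Total abundance scalar (> 0); arbitrary area units.
#' @param isotype Light-chain isotype of the simulated molecule.
#' @return Object of class `ground_truth`.
#' @examples
#' ground_truth(thiol = c(`2xSH` = 1, `1xSH1xCys` = 0, `2xCys` = 0, iDSB = 0))
#' @export
ground_truth <- function(thiol = c("2xSH" = 0.10, "1xSH1xCys" = 0.20,
                                   "2xCys" = 0.50, "iDSB" = 0.20),
                         glyco = c(Man5 = 0.04, G0 = 0.04, "G1F-GN" = 0.03,
                                   G0F = 0.30, G1F = 0.25, "G1F-GN+NAc" = 0.01,
                                   G2F = 0.10, G1FS = 0.09, G2FB = 0.04,
                                   G2FS = 0.07, G2FS2 = 0.03),
                         reduction = c(heavy_light = 0.02, heavy_heavy = 0.01),
                         fragmentation = c(Frag1 = 0.01, Frag2 = 0.005,
                                           Frag3 = 0.01, Frag4 = 0.005),
                         abundance = 1,
                         isotype = c("lambda", "kappa")) {
  isotype <- match.arg(isotype)
  thiol <- .check_simplex(thiol, .THIOL_STATES, "thiol")
  glyco <- .check_simplex(glyco, .GLYCOFORMS, "glyco")
  reduction <- .check_unit_range(reduction, c("heavy_light", "heavy_heavy"),
                                 "reduction")
  fragmentation <- .check_unit_range(fragmentation, .FRAG_SITES, "fragmentation")
  if (fragmentation[["Frag2"]] + fragmentation[["Frag4"]] > 1) {
    stop("Frag2 + Frag4 fractions exceed 1; they share the wildtype parent",
         call. = FALSE)
  }
  if (!is.finite(abundance) || abundance <= 0) {
    stop("abundance must be a positive scalar", call. = FALSE)
  }
  structure(list(thiol = thiol, glyco = glyco, reduction = reduction,
                 fragmentation = fragmentation, abundance = abundance,
                 isotype = isotype),
            class = "ground_truth")
}

.check_simplex <- function(x, states, what, tol = 1e-9) {
  if (!all(states %in% names(x))) {
    stop(what, " proportions must name all of: ", paste(states, collapse = ", "),
         call. = FALSE)
  }
  x <- x[states]
  if (any(x < -tol) || abs(sum(x) - 1) > tol) {
    stop(what, " proportions must be non-negative and sum to 1", call. = FALSE)
  }
  pmax(x, 0)
}

.check_unit_range <- function(x, states, what) {
  if (!all(states %in% names(x))) {
    stop(what, " fractions must name all of: ", paste(states, collapse = ", "),
         call. = FALSE)
  }
  x <- x[states]
  if (any(x < 0 | x > 1)) stop(what, " fractions must lie in [0, 1]", call. = FALSE)
  x
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth, %s isotype, abundance %g>\n", x$isotype, x$abundance))
  cat("  thiol: ", paste(sprintf("%s %.3f", names(x$thiol), x$thiol), collapse = ", "), "\n")
  cat("  sialylated glycans:", sprintf("%.3f", sum(x$glyco[intersect(names(x$glyco), .sialylated_glycoforms)])), "\n")
  cat("  reduction:", paste(sprintf("%s %.3f", names(x$reduction), x$reduction), collapse = ", "), "\n")
  invisible(x)
}

#' Instrument model for the simulator
#'
#' @param response_factors Named per-analyte multiplicative response factors
#'   (relative ionization propensity; unnamed analytes default to 1, the
#'   reference convention).
#' @param bias_quadratic Named second-order bias coefficients c2: expected
#'   response is `RF * x + c2 * x^2` on the relative-abundance scale.
#' @param noise_cv Coefficient of variation of multiplicative lognormal noise
#'   (default 1 %).
#' @param rt_jitter_sd SD of retention-time jitter (minutes).
#' @param peak_sigma Gaussian chromatographic peak SD (minutes).
#' @param insource In-source fragmentation model parameters: `f_max`, logistic
#'   midpoint/scale in desolvation temperature, and linear coefficients for
#'   desolvation gas flow and capillary voltage.
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(response_factors = NULL, bias_quadratic = NULL,
                             noise_cv = 0.01, rt_jitter_sd = 0.02,
                             peak_sigma = 0.05,
                             insource = list(f_max = 0.30, temp_mid = 420,
                                             temp_scale = 25,
                                             gasflow_coef = 0.002,
                                             capillary_coef = 0.5)) {
  if (!is.null(response_factors) && any(response_factors <= 0)) {
    stop("response factors must be > 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(response_factors = response_factors,
                 bias_quadratic = bias_quadratic,
                 noise_cv = noise_cv, rt_jitter_sd = rt_jitter_sd,
                 peak_sigma = peak_sigma, insource = insource),
            class = "instrument_model")
}

#' Electrospray source parameters
#'
#' @param capillary_kV Capillary voltage (kV).
#' @param desolvation_temp_C Desolvation temperature (deg C).
#' @param desolvation_gasflow_Lh Desolvation gas flow (L/h).
#' @param cone_V Cone voltage (V).
#' @param source_offset_V Source offset (V).
#' @param collision_V Collision energy (V).
#' @return Object of class `source_params`.
#' @export
source_params <- function(capillary_kV = 3, desolvation_temp_C = 400,
                          desolvation_gasflow_Lh = 400, cone_V = 45,
                          source_offset_V = 55, collision_V = 75) {
  vals <- c(capillary_kV = capillary_kV,
            desolvation_temp_C = desolvation_temp_C,
            desolvation_gasflow_Lh = desolvation_gasflow_Lh,
            cone_V = cone_V, source_offset_V = source_offset_V,
            collision_V = collision_V)
  if (any(!is.finite(vals))) stop("source parameters must be finite", call. = FALSE)
  structure(as.list(vals), class = "source_params")
}

#' In-source fragmentation fraction
#'
#' Fraction of a sialylated glycoform's signal that leaks down its
#' decomposition chain at the given source settings: a scaled logistic in
#' desolvation temperature plus linear terms in desolvation gas flow and
#' capillary voltage, clipped to `[0, f_max]`. Monotone nondecreasing in
#' desolvation temperature at fixed other parameters.
#'
#' @param source A `source_params`.
#' @param instrument An `instrument_model` (its `insource` parameters).
#' @return Leak fraction in `[0, 1]`.
#' @export
insource_fraction <- function(source, instrument = instrument_model()) {
  p <- instrument$insource
  lin <- (source$desolvation_temp_C - p$temp_mid) / p$temp_scale +
    p$gasflow_coef * (source$desolvation_gasflow_Lh - 400) +
    p$capillary_coef * (source$capillary_kV - 3)
  f <- p$f_max * stats::plogis(lin)
  min(max(f, 0), 1)
}

# Closed-form expected analyte signal (before response factors and noise):
# the oracle every round-trip test leans on.
.expected_analyte_signal <- function(truth) {
  A <- truth$abundance
  r <- truth$reduction
  f <- truth$fragmentation
  sig <- c(
    stats::setNames(A * (1 - r[["heavy_heavy"]]) * truth$thiol, .THIOL_STATES),
    heavy_reduced = A * r[["heavy_heavy"]],
    stats::setNames(A * truth$glyco, names(truth$glyco)),
    lambda_linked = 0, lambda_reduced = 0, kappa_linked = 0, kappa_reduced = 0,
    wildtype = A * (1 - f[["Frag2"]] - f[["Frag4"]]),
    Frag1 = A * f[["Frag1"]], Frag2 = A * f[["Frag2"]],
    Frag3 = A * f[["Frag3"]], Frag4 = A * f[["Frag4"]],
    standard = A
  )
  pre <- if (truth$isotype == "lambda") "lambda" else "kappa"
  sig[[paste0(pre, "_linked")]] <- A * (1 - r[["heavy_light"]])
  sig[[paste0(pre, "_reduced")]] <- A * r[["heavy_light"]]
  sig
}

#' Closed-form attribute report implied by a ground truth
#'
#' What quantitation must return on noiseless data with unit response factors:
#' the oracle for round-trip identity tests. Values are percentages (or the
#' vs-standard ratio for Frag1/Frag3).
#'
#' @param truth A `ground_truth`.
#' @return data.frame with `attribute_class`, `analyte`, `value_percent`, `mode`.
#' @export
truth_report <- function(truth) {
  f <- truth$fragmentation
  intact <- 1 - f[["Frag2"]] - f[["Frag4"]]
  df <- rbind(
    data.frame(attribute_class = "thiol_state", analyte = .THIOL_STATES,
               value_percent = 100 * as.numeric(truth$thiol),
               mode = "percent-of-states", stringsAsFactors = FALSE),
    data.frame(attribute_class = "glycosylation",
               analyte = c(names(truth$glyco), "sialylated"),
               value_percent = 100 * c(as.numeric(truth$glyco),
                                       sum(truth$glyco[intersect(names(truth$glyco),
                                                                 .sialylated_glycoforms)])),
               mode = "percent-of-glycoforms", stringsAsFactors = FALSE),
    data.frame(attribute_class = "partial_reduction",
               analyte = c("heavy_light", "heavy_heavy"),
               value_percent = 100 * as.numeric(truth$reduction),
               mode = "percent-reduced", stringsAsFactors = FALSE),
    data.frame(attribute_class = "fragmentation",
               analyte = .FRAG_SITES,
               value_percent = 100 * c(f[["Frag1"]],
                                       f[["Frag2"]] / (f[["Frag2"]] + intact),
                                       f[["Frag3"]],
                                       f[["Frag4"]] / (f[["Frag4"]] + intact)),
               mode = c("vs-standard", "vs-parent", "vs-standard", "vs-parent"),
               stringsAsFactors = FALSE)
  )
  rownames(df) <- NULL
  df
}

#' Simulate an MRM peak table
#'
#' Expected area of analyte i is `abundance * fraction_i * RF_i` (plus the
#' optional quadratic bias term), split equally across the analyte's
#' transitions, then multiplied by lognormal noise with the stated CV (unit
#' mean). Identical seeds give identical tables.
#'
#' @param truth A `ground_truth`, or a list of them (one per sample).
#' @param instrument An `instrument_model`.
#' @param panel An `attribute_panel`.
#' @param n_samples Number of samples (ignored when `truth` is a list).
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return A peak table: data.frame `sample_id, compound_id, rt_min, area`.
#' @export
simulate_peak_table <- function(truth, instrument = instrument_model(),
                                panel = build_default_panel(),
                                n_samples = 1L, seed = NULL) {
  truths <- if (inherits(truth, "ground_truth")) {
    rep(list(truth), n_samples)
  } else {
    stopifnot(all(vapply(truth, inherits, logical(1), "ground_truth")))
    truth
  }
  if (!length(truths)) stop("need at least one sample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  analytes <- panel_analyte(panel$compound_id)
  n_trans <- table(analytes)
  mid <- (panel$rt_start_min + panel$rt_end_min) / 2
  rf_of <- function(a) {
    rf <- instrument$response_factors
    if (!is.null(rf) && a %in% names(rf)) rf[[a]] else 1
  }
  c2_of <- function(a) {
    b <- instrument$bias_quadratic
    if (!is.null(b) && a %in% names(b)) b[[a]] else 0
  }
  out <- vector("list", length(truths))
  for (s in seq_along(truths)) {
    sig <- .expected_analyte_signal(truths[[s]])
    x <- vapply(analytes, function(a) {
      v <- if (a %in% names(sig)) sig[[a]] else 0
      (rf_of(a) * v + c2_of(a) * v^2) / as.numeric(n_trans[[a]])
    }, numeric(1))
    if (instrument$noise_cv > 0) {
      sdl <- sqrt(log(1 + instrument$noise_cv^2))
      x <- x * stats::rlnorm(length(x), meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    rt <- mid + if (instrument$rt_jitter_sd > 0) {
      stats::rnorm(nrow(panel), 0, instrument$rt_jitter_sd)
    } else 0
    # keep apexes inside their integration windows
    halfw <- (panel$rt_end_min - panel$rt_start_min) / 2
    margin <- pmax(halfw - 3 * instrument$peak_sigma, 0)
    rt <- pmin(pmax(rt, mid - margin), mid + margin)
    out[[s]] <- data.frame(sample_id = sprintf("S%03d", s),
                           compound_id = panel$compound_id,
                           rt_min = rt, area = pmax(x, 0),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Blend series between two ground truths
#'
#' Convex combinations of all proportion fields: at level l the truth is
#' `(1 - l) * a + l * b`. Level 0 returns `a` exactly. This reproduces the
#' spike-in designs used for calibration (enriched material titrated into a
#' reference material at known levels).
#'
#' @param endpoint_a,endpoint_b `ground_truth` endpoints (same isotype).
#' @param levels Numeric levels in `[0, 1]`.
#' @return List of `ground_truth`, one per level.
#' @export
generate_blend_series <- function(endpoint_a, endpoint_b,
                                  levels = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(endpoint_a, "ground_truth"),
            inherits(endpoint_b, "ground_truth"))
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]", call. = FALSE)
  if (endpoint_a$isotype != endpoint_b$isotype) {
    stop("blend endpoints must share an isotype", call. = FALSE)
  }
  lapply(levels, function(l) {
    mix <- function(field) (1 - l) * endpoint_a[[field]] + l * endpoint_b[[field]]
    ground_truth(thiol = mix("thiol"), glyco = mix("glyco"),
                 reduction = mix("reduction"),
                 fragmentation = mix("fragmentation"),
                 abundance = mix("abundance"), isotype = endpoint_a$isotype)
  })
}

# one-step decomposition chain: donor -> acceptor (one NeuAc, then one Hex)
.insource_chain <- c("G2FS2" = "G2FS", "G2FS" = "G2F", "G1FS" = "G1F")

#' Apply in-source fragmentation to a peak table
#'
#' Moves a fraction f (determined by the source parameters) of each sialylated
#' glycoform's area one step down its decomposition chain
#' (G2FS2 -> G2FS -> G2F; G1FS -> G1F), applied simultaneously to the input
#' areas, so total glycoform area is conserved exactly. f = 0 is the identity.
#'
#' @param peak_table Peak table from [simulate_peak_table()].
#' @param panel The panel (identifies the glycosylation compounds).
#' @param source `source_params` at which the leak fraction is evaluated.
#' @param instrument `instrument_model` carrying the in-source coefficients.
#' @return Peak table with leaked glycoform areas.
#' @export
apply_insource_model <- function(peak_table, panel = build_default_panel(),
                                 source = source_params(),
                                 instrument = instrument_model()) {
  gly <- panel$compound_id[panel$attribute_class == "glycosylation"]
  if (!length(gly)) stop("panel has no glycosylation compounds", call. = FALSE)
  f <- insource_fraction(source, instrument)
  if (f == 0) return(peak_table)
  out <- peak_table
  for (s in unique(out$sample_id)) {
    idx <- which(out$sample_id == s & out$compound_id %in% gly)
    a <- stats::setNames(out$area[idx], panel_analyte(out$compound_id[idx]))
    moved <- stats::setNames(numeric(length(a)), names(a))
    for (donor in intersect(names(.insource_chain), names(a))) {
      acceptor <- .insource_chain[[donor]]
      if (!acceptor %in% names(a)) next
      moved[donor] <- moved[donor] - f * a[[donor]]
      moved[acceptor] <- moved[acceptor] + f * a[[donor]]
    }
    out$area[idx] <- as.numeric(a + moved)
  }
  out
}

#' Simulate SRM chromatogram traces from a peak table
#'
#' One Gaussian peak per (sample, compound), centered at the table's observed
#' retention time (already jittered and truncated to keep the apex inside the
#' window), with SD `peak_sigma` shrunk if needed so +/- 4 SD fits the window.
#' Intensities are scaled by the truncated-Gaussian mass so the trapezoidal
#' integral over the window reproduces the table area.
#'
#' @param peak_table Peak table.
#' @param panel Panel supplying the RT windows.
#' @param dt Sampling interval (minutes); must be finer than the peak SD.
#' @param instrument Instrument model (peak shape).
#' @return Long data.frame `sample_id, compound_id, time_min, intensity`.
#' @export
simulate_chromatograms <- function(peak_table, panel = build_default_panel(),
                                   dt = 0.002,
                                   instrument = instrument_model()) {
  if (dt >= instrument$peak_sigma) {
    stop("sampling interval is wider than the peak width", call. = FALSE)
  }
  win <- stats::setNames(split(cbind(panel$rt_start_min, panel$rt_end_min),
                               seq_len(nrow(panel))), panel$compound_id)
  out <- vector("list", nrow(peak_table))
  for (i in seq_len(nrow(peak_table))) {
    cid <- peak_table$compound_id[i]
    if (!cid %in% names(win)) stop("compound not in panel: ", cid, call. = FALSE)
    w <- win[[cid]]
    tt <- seq(w[1], w[2], by = dt)
    apex <- min(max(peak_table$rt_min[i], w[1]), w[2])
    sigma <- min(instrument$peak_sigma,
                 max((min(apex - w[1], w[2] - apex)) / 4, dt * 2))
    area <- peak_table$area[i]
    y <- if (area > 0) {
      mass <- stats::pnorm(w[2], apex, sigma) - stats::pnorm(w[1], apex, sigma)
      area * stats::dnorm(tt, apex, sigma) / mass
    } else {
      numeric(length(tt))
    }
    out[[i]] <- data.frame(sample_id = peak_table$sample_id[i],
                           compound_id = cid, time_min = tt, intensity = y,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
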