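# Design-space analysis: efficiency-vs-dG response curves, dynamic range,
# truncation scans, condition sweeps.

#' Free energy-efficiency response curve
#'
#' Evaluates the equivalent amplification efficiency over a grid of initial
#' (binding-region) free energies at a fixed tag free energy, one
#' [run_pcr()] evaluation per grid point.
#'
#' @param dg_grid Sorted numeric grid of initial dG values, kcal/mol
#'   (>= 10 points spanning the transition are recommended).
#' @param tag_dG Tag free energy, kcal/mol (0 = conventional primer).
#' @param protocol List with `conditions` and `cycles`, as returned by
#'   [ref_protocol()].
#' @param opposite_primer_efficiency Fixed opposite-primer efficiency.
#' @param anneal Anneal method passed to [run_pcr()].  The default
#'   `"equilibrium"` is indistinguishable from the ODE at the reference
#'   30-s window (the window is fully equilibrated; verified in the test
#'   suite) and much faster for large scans.
#' @return A data.frame of class `pa_curve` with columns `dG` and
#'   `efficiency`, and the protocol stored in attributes.
#' @examples
#' efficiency_curve(seq(-12, -4, by = 1), tag_dG = -12)
#' @export
efficiency_curve <- function(dg_grid, tag_dG = 0, protocol = ref_protocol(),
                             opposite_primer_efficiency = 1,
                             anneal = c("equilibrium", "ode")) {
  anneal <- match.arg(anneal)
  if (is.unsorted(dg_grid)) stop("dg_grid must be sorted increasing")
  eff <- vapply(dg_grid, function(dg) {
    run_pcr(pa_primer(dG_binding = dg, dG_tag = tag_dG),
            opposite_primer_efficiency = opposite_primer_efficiency,
            cycles = protocol$cycles, conditions = protocol$conditions,
            anneal = anneal)$equivalent_efficiency
  }, numeric(1))
  out <- data.frame(dG = dg_grid, efficiency = eff)
  attr(out, "tag_dG") <- tag_dG
  attr(out, "protocol") <- protocol
  class(out) <- c("pa_curve", "data.frame")
  out
}

# monotone interpolant of a response curve (efficiency decreasing in dG)
.curve_fun <- function(curve) {
  stats::splinefun(curve$dG, curve$efficiency, method = "hyman")
}

#' Dynamic range of a response curve
#'
#' Width (in kcal/mol of initial dG) of the region where the equivalent
#' efficiency transitions between two levels, by default 20% and 80%.
#' A monotone interpolant is fitted through the curve (Hyman-filtered
#' monotone cubic spline by default, or a symmetric logistic sigmoid via
#' `method = "logistic"`) and the two crossings are read off; the curve is
#' asymmetric around its midpoint, which is why the shape-preserving
#' spline is the default reader.
#'
#' @param curve A `pa_curve` from [efficiency_curve()].
#' @param lower,upper Efficiency levels defining the window.
#' @param method `"spline"` (monotone interpolation) or `"logistic"`
#'   (two-parameter sigmoid fit).
#' @return An object of class `pa_dynamic_range`: list with `width`
#'   (kcal/mol), `dG_upper_eff` (dG at the `upper` crossing),
#'   `dG_lower_eff` (dG at the `lower` crossing), `lower`, `upper`,
#'   `method`.
#' @export
dynamic_range <- function(curve, lower = 0.2, upper = 0.8,
                          method = c("spline", "logistic")) {
  method <- match.arg(method)
  rng <- range(curve$dG)
  emin <- min(curve$efficiency)
  emax <- max(curve$efficiency)
  if (emin > lower || emax < upper) {
    stop("range not bracketed: curve spans efficiencies [",
         signif(emin, 3), ", ", signif(emax, 3), "] but crossings at ",
         lower, " and ", upper, " are required")
  }
  if (method == "logistic") {
    fit <- stats::nls(
      efficiency ~ 1 / (1 + exp((dG - m) / w)),
      data = curve, start = list(m = mean(rng), w = 0.5),
      control = stats::nls.control(maxiter = 500, warnOnly = TRUE)
    )
    f <- function(x) stats::predict(fit, newdata = data.frame(dG = x))
  } else {
    f <- .curve_fun(curve)
  }
  cross <- function(level) {
    stats::uniroot(function(x) f(x) - level, interval = rng,
                   tol = 1e-10)$root
  }
  at_upper <- cross(upper)
  at_lower <- cross(lower)
  obj <- list(width = at_lower - at_upper,
              dG_upper_eff = at_upper, dG_lower_eff = at_lower,
              lower = lower, upper = upper, method = method)
  class(obj) <- "pa_dynamic_range"
  obj
}

#' @export
print.pa_dynamic_range <- function(x, ...) {
  cat(sprintf(
    "dynamic range: %.3f kcal/mol (dG %.2f at %.0f%% -> %.2f at %.0f%% efficiency, %s)\n",
    x$width, x$dG_upper_eff, 100 * x$upper, x$dG_lower_eff, 100 * x$lower,
    x$method))
  invisible(x)
}

#' Transition window of a primer system
#'
#' The initial-dG interval over which the equivalent efficiency falls from
#' `upper` to `lower` (defaults 0.95 to 0.05) -- the region where primers
#' respond to design changes at all.  Used to place random-primer
#' ensembles for truncation statistics.
#'
#' @inheritParams efficiency_curve
#' @param lower,upper Efficiency levels bounding the window.
#' @param dg_search Grid over which the curve is evaluated.
#' @return Numeric `c(lo, hi)`: dG at the `upper` crossing and at the
#'   `lower` crossing.
#' @export
transition_window <- function(tag_dG = 0, protocol = ref_protocol(),
                              lower = 0.05, upper = 0.95,
                              dg_search = seq(-18, 2, by = 0.25)) {
  curve <- efficiency_curve(dg_search, tag_dG, protocol)
  dr <- dynamic_range(curve, lower = lower, upper = upper)
  c(dr$dG_upper_eff, dr$dG_lower_eff)
}

#' Truncation scan of a primer
#'
#' Progressively removes bases from the 5' (tag-junction) end of the
#' binding region -- the 3' terminus must stay extendable -- recomputing
#' thermodynamics, equivalent efficiency and Ct at each step.
#'
#' @param primer A [pa_primer()] carrying a real `binding_region`
#'   sequence (and optionally a `tag` sequence).
#' @param n_truncations Number of single-base truncation steps; the
#'   remaining binding region must stay >= 8 nt.
#' @param protocol As in [efficiency_curve()].
#' @param detection_threshold,ct_cycles,cap Ct settings: threshold in
#'   copies, simulated cycle count, and the reporting cap.
#' @param params NN parameter set.
#' @param anneal Anneal method for the simulations.
#' @return data.frame with columns `truncation`, `sequence`, `dG`,
#'   `efficiency`, `Ct`.
#' @export
truncation_scan <- function(primer, n_truncations, protocol = ref_protocol(),
                            detection_threshold = 1e10, ct_cycles = 50,
                            cap = 50, params = nn_params(),
                            anneal = c("equilibrium", "ode")) {
  anneal <- match.arg(anneal)
  stopifnot(inherits(primer, "pa_primer"))
  if (is.null(primer$binding_region)) {
    stop("truncation_scan needs a primer with a sequence binding region")
  }
  seqlen <- nchar(primer$binding_region)
  if (seqlen - n_truncations < 8) {
    stop("over-truncation: binding region must keep >= 8 nt (",
         seqlen, " nt minus ", n_truncations, " truncations)")
  }
  conds <- protocol$conditions
  tag_dG <- primer$dG_tag
  rows <- lapply(0:n_truncations, function(k) {
    s <- substr(primer$binding_region, k + 1, seqlen)
    th <- duplex_thermo(s, conds, params)
    pr <- pa_primer(binding_region = s, dG_binding = th$dG, dG_tag = tag_dG)
    sim <- run_pcr(pr, cycles = protocol$cycles, conditions = conds,
                   anneal = anneal)
    ct_sim <- run_pcr(pr, cycles = ct_cycles, conditions = conds,
                      anneal = anneal)
    data.frame(truncation = k, sequence = s, dG = th$dG,
               efficiency = sim$equivalent_efficiency,
               Ct = ct_from_sim(ct_sim, detection_threshold, cap = cap))
  })
  do.call(rbind, rows)
}

#' Median efficiency drop per single-base truncation
#'
#' For an ensemble of primers, removes 5' bases one at a time
#' (`n_truncations` events per primer) and records the change in
#' equivalent amplification efficiency per event.  The headline statistic
#' is the median relative drop, `(e_before - e_after) / e_before`,
#' expressed in percent; the median absolute drop (percentage points) is
#' also returned.
#'
#' @param primers Character vector of binding-region sequences (e.g. from
#'   [generate_primer_panel()]), or a data.frame with a `sequence`
#'   column.
#' @param tag_dG Tag free energy shared by the ensemble, kcal/mol.
#' @param protocol As in [efficiency_curve()].
#' @param n_truncations Truncation events per primer (default 3).
#' @param params NN parameter set.
#' @param anneal Anneal method.
#' @param min_eff Events whose pre-truncation efficiency falls below this
#'   floor are dropped (the relative change is ill-conditioned there).
#' @return List with `median_drop_pct`, `median_abs_drop_points`, and the
#'   per-event `events` data.frame.
#' @export
median_truncation_drop <- function(primers, tag_dG = 0,
                                   protocol = ref_protocol(),
                                   n_truncations = 3, params = nn_params(),
                                   anneal = c("equilibrium", "ode"),
                                   min_eff = 1e-4) {
  anneal <- match.arg(anneal)
  if (is.data.frame(primers)) primers <- primers$sequence
  if (!length(primers)) stop("empty primer ensemble")
  conds <- protocol$conditions
  eval_e <- function(s) {
    dg <- duplex_thermo(s, conds, params)$dG
    run_pcr(pa_primer(dG_binding = dg, dG_tag = tag_dG),
            cycles = protocol$cycles, conditions = conds,
            anneal = anneal)$equivalent_efficiency
  }
  events <- list()
  for (p in primers) {
    s <- toupper(p)
    e0 <- eval_e(s)
    for (k in seq_len(n_truncations)) {
      if (nchar(s) - 1 < 8) break
      s1 <- substr(s, 2, nchar(s))
      e1 <- eval_e(s1)
      if (e0 >= min_eff) {
        events[[length(events) + 1L]] <- data.frame(
          primer = p, step = k, e_before = e0, e_after = e1,
          rel_drop = (e0 - e1) / e0, abs_drop = e0 - e1
        )
      }
      s <- s1
      e0 <- e1
    }
  }
  events <- do.call(rbind, events)
  list(
    median_drop_pct = 100 * stats::median(events$rel_drop),
    median_abs_drop_points = 100 * stats::median(events$abs_drop),
    events = events
  )
}

#' Temperature / extension-time condition sweep
#'
#' Re-derives each primer free energy from its sequence at every
#' temperature (dG(T) = dH - T*dS/1000 with the salt-corrected entropy)
#' and evaluates the equivalent efficiency over the full temperature x
#' time grid.
#'
#' @param primer A sequence-bearing [pa_primer()].
#' @param temperatures Numeric vector, degrees C.
#' @param times Numeric vector, seconds.
#' @param protocol Base protocol; its temperature and extension time are
#'   overridden cell by cell.
#' @param params NN parameter set.
#' @param anneal Anneal method.  The default here is `"ode"` because short
#'   extension times are exactly where the finite anneal window matters.
#' @return data.frame with columns `temperature`, `time`, `dG`,
#'   `tag_dG`, `efficiency`.
#' @export
condition_sweep <- function(primer, temperatures, times,
                            protocol = ref_protocol(), params = nn_params(),
                            anneal = c("ode", "equilibrium")) {
  anneal <- match.arg(anneal)
  stopifnot(inherits(primer, "pa_primer"))
  if (is.null(primer$binding_region)) {
    stop("condition_sweep needs sequences so that dG(T) can be re-derived")
  }
  has_tag <- !is.null(primer$tag) && nzchar(primer$tag) &&
    !identical(primer$tag, "<by-dG>")
  grid <- expand.grid(temperature = temperatures, time = times)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    conds <- protocol$conditions
    conds$temperature <- grid$temperature[i]
    conds$extension_time <- grid$time[i]
    dg <- duplex_thermo(primer$binding_region, conds, params)$dG
    tg <- if (has_tag) tag_free_energy(primer$tag, conds, params)
          else primer$dG_tag
    sim <- run_pcr(pa_primer(dG_binding = dg, dG_tag = tg),
                   cycles = protocol$cycles, conditions = conds,
                   anneal = anneal)
    data.frame(temperature = conds$temperature, time = conds$extension_time,
               dG = dg, tag_dG = tg, efficiency = sim$equivalent_efficiency)
  })
  do.call(rbind, rows)
}
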