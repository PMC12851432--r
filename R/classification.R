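#' The eight-element EDS analysis set
#'
#' Carbon and oxygen are excluded because the polycarbonate filter substrate
#' contaminates their peaks; only elements commonly found in zeolites are
#' retained.
#' @export
EDS_ELEMENTS <- c("Si", "Al", "Mg", "Na", "K", "Ca", "Fe", "Cl")

#' Renormalize a raw elemental mass-percent vector
#'
#' Restricts the input to the eight-element set and rescales to a sum of
#' 100. Missing elements are taken as zero; negative values are an error.
#'
#' @param raw Named numeric vector of mass percentages (any subset of
#'   [EDS_ELEMENTS]; other names are dropped).
#' @param acquisition_time EDS acquisition time in seconds (metadata;
#'   default 10, the high-throughput setting).
#' @return An object of class `"eds_composition"`: list with `mass_pct`
#'   (named vector over [EDS_ELEMENTS], summing to 100),
#'   `acquisition_time`, `renormalized = TRUE`.
#' @export
renormalize <- function(raw, acquisition_time = 10) {
  if (is.null(names(raw))) stop("'raw' must be a named vector of elements")
  v <- setNames(numeric(length(EDS_ELEMENTS)), EDS_ELEMENTS)
  keep <- intersect(names(raw), EDS_ELEMENTS)
  v[keep] <- as.numeric(raw[keep])
  if (any(!is.finite(v)) || any(v < 0))
    stop("mass percentages must be finite and non-negative")
  s <- sum(v)
  if (s <= 0) stop("no analyzable elements: all eight mass percentages are zero")
  structure(list(mass_pct = v / s * 100,
                 acquisition_time = acquisition_time,
                 renormalized = TRUE),
            class = "eds_composition")
}

#' Tetrahedral silicon ratio Tsi = Si/(Si + Al)
#'
#' Screening statistic separating silica-rich frameworks; about 0.75 on a
#' mass basis (0.744 on an atomic basis) for the reference erionite. The
#' formula applies to any proportional basis: pass renormalized mass
#' percentages for particle screening or atomic proportions for
#' bulk-formula checks.
#'
#' @param comp An `"eds_composition"` from [renormalize()], or a named
#'   numeric vector containing `Si` and `Al` entries.
#' @return Si/(Si+Al) in `[0, 1]`, or `NA_real_` when Si + Al = 0 (the
#'   particle is then routed to the non-zeolite branch of the classifier).
#' @export
compute_tsi <- function(comp) {
  v <- if (inherits(comp, "eds_composition")) comp$mass_pct else comp
  si <- as.numeric(v[["Si"]])
  al <- as.numeric(v[["Al"]])
  if (si + al <= 0) return(NA_real_)
  si / (si + al)
}

#' Classification rule gates
#'
#' Numeric gates of the particle-classification decision tree. The defaults
#' are screening values, not mineralogical identifications: the Tsi window
#' (0.68, 0.79) brackets the mass-basis Tsi of reference erionite (~0.75)
#' while excluding high-silica zeolites such as mordenite (~0.84);
#' `cl_salt_min` catches marine-aerosol halides; `al_trace_max` and
#' `si_min_silica` isolate near-pure silica; `cation_min` requires the
#' extra-framework cations (Na+K+Ca+Mg) that distinguish a zeolite from a
#' feldspar-like aluminosilicate; `fe_rich_min` catches iron oxides.
#'
#' @param tsi_window Length-2 numeric `(low, high)`, `0 <= low < high <= 1`:
#'   erionite-like band of Tsi.
#' @param cl_salt_min Mass% Cl at or above which a particle is a halide salt.
#' @param al_trace_max Mass% Al at or below which a Si-rich particle is silica.
#' @param si_min_silica Minimum mass% Si for the silica rule.
#' @param cation_min Minimum combined Na+K+Ca+Mg mass% for the zeolite branch.
#' @param fe_rich_min Mass% Fe at or above which a residual particle is
#'   Fe-rich.
#' @return An object of class `"classification_rules"`.
#' @export
classification_rules <- function(tsi_window = c(0.68, 0.79),
                                 cl_salt_min = 15, al_trace_max = 2,
                                 si_min_silica = 30, cation_min = 2,
                                 fe_rich_min = 30) {
  tsi_window <- as.numeric(tsi_window)
  if (length(tsi_window) != 2L || tsi_window[1] < 0 || tsi_window[2] > 1 ||
      tsi_window[1] >= tsi_window[2])
    stop("'tsi_window' must be (low, high) with 0 <= low < high <= 1")
  gates <- c(cl_salt_min, al_trace_max, si_min_silica, cation_min, fe_rich_min)
  if (any(!is.finite(gates)) || any(gates < 0) || any(gates > 100))
    stop("all mass-percent gates must lie in [0, 100]")
  structure(list(tsi_window = tsi_window, cl_salt_min = cl_salt_min,
                 al_trace_max = al_trace_max, si_min_silica = si_min_silica,
                 cation_min = cation_min, fe_rich_min = fe_rich_min),
            class = "classification_rules")
}

#' Read classification rules from a YAML or JSON file
#' @param path File with any subset of the [classification_rules()] fields.
#' @return A `"classification_rules"` object.
#' @export
read_classification_rules <- function(path) {
  cfg <- read_config_file(path)
  do.call(classification_rules, cfg)
}

#' The classification label set
#' @export
CLASS_LABELS <- c("erionite_like_zeolite", "other_zeolite", "silica",
                  "salt_halide", "fe_rich_mineral", "unclassified_mineral",
                  "non_fiber")

#' Classify one particle from morphology and composition
#'
#' Deterministic decision tree, rules evaluated strictly in order with first
#' match winning:
#' 1. not a fiber -> `non_fiber`;
#' 2. Cl at/above `cl_salt_min` -> `salt_halide`;
#' 3. Si at/above `si_min_silica` with Al at/below `al_trace_max` -> `silica`;
#' 4. Si > 0, Al above `al_trace_max`, Na+K+Ca+Mg at/above `cation_min` ->
#'    zeolite branch: `erionite_like_zeolite` when Tsi falls inside
#'    `tsi_window` (open interval), else `other_zeolite`;
#' 5. Fe at/above `fe_rich_min` -> `fe_rich_mineral`;
#' 6. otherwise `unclassified_mineral`.
#'
#' `erionite_like_zeolite` is a screening label: compositional screening
#' cannot distinguish erionite from offretite, and confirmation requires
#' TEM/SAED.
#'
#' @param is_fiber Logical morphology verdict from [apply_fiber_criteria()].
#' @param comp An `"eds_composition"` from [renormalize()].
#' @param rules A [classification_rules()] object.
#' @return List with `label`, `tsi`, and `rule_trace` (character vector of
#'   rule ids fired, in order).
#' @export
classify_particle <- function(is_fiber, comp, rules = classification_rules()) {
  if (!inherits(comp, "eds_composition") || !isTRUE(comp$renormalized))
    stop("'comp' must be a renormalized eds_composition (see renormalize())")
  stopifnot(inherits(rules, "classification_rules"))
  v <- comp$mass_pct
  tsi <- compute_tsi(comp)
  trace <- character(0)
  lab <- NULL
  if (!isTRUE(is_fiber)) {
    trace <- "fiber_gate:fail"
    lab <- "non_fiber"
  } else {
    trace <- "fiber_gate:pass"
    if (v[["Cl"]] >= rules$cl_salt_min) {
      trace <- c(trace, "cl_gate:hit")
      lab <- "salt_halide"
    } else {
      trace <- c(trace, "cl_gate:miss")
      if (v[["Si"]] >= rules$si_min_silica && v[["Al"]] <= rules$al_trace_max) {
        trace <- c(trace, "silica_gate:hit")
        lab <- "silica"
      } else {
        trace <- c(trace, "silica_gate:miss")
        cations <- v[["Na"]] + v[["K"]] + v[["Ca"]] + v[["Mg"]]
        if (v[["Si"]] > 0 && v[["Al"]] > rules$al_trace_max &&
            cations >= rules$cation_min) {
          trace <- c(trace, "zeolite_gate:hit")
          if (!is.na(tsi) && tsi > rules$tsi_window[1] &&
              tsi < rules$tsi_window[2]) {
            trace <- c(trace, "tsi_window:in")
            lab <- "erionite_like_zeolite"
          } else {
            trace <- c(trace, "tsi_window:out")
            lab <- "other_zeolite"
          }
        } else {
          trace <- c(trace, "zeolite_gate:miss")
          if (v[["Fe"]] >= rules$fe_rich_min) {
            trace <- c(trace, "fe_gate:hit")
            lab <- "fe_rich_mineral"
          } else {
            trace <- c(trace, "fe_gate:miss")
            lab <- "unclassified_mineral"
          }
        }
      }
    }
  }
  list(label = lab, tsi = tsi, rule_trace = trace)
}

#' Classify a particle table against an EDS composition table
#'
#' Joins detected particles with their EDS rows by `particle_id` and applies
#' [classify_particle()] to each. Every particle must have exactly one EDS
#' row and vice versa; orphans on either side are an error (listed in the
#' message), mirroring the instrument invariant that EDS is acquired per
#' detected particle.
#'
#' @param particles Data frame from [apply_fiber_criteria()] (needs
#'   `particle_id`, `is_fiber`).
#' @param eds Data frame with `particle_id` and the eight element columns
#'   (mass%, un- or renormalized); an optional `acquisition_time_s` column
#'   is carried through.
#' @param rules A [classification_rules()] object.
#' @return `particles` with columns `label`, `tsi`, `rule_trace`
#'   (semicolon-joined rule ids).
#' @export
classify_particles <- function(particles, eds, rules = classification_rules()) {
  stopifnot(is.data.frame(particles), is.data.frame(eds))
  missing_eds <- setdiff(particles$particle_id, eds$particle_id)
  extra_eds <- setdiff(eds$particle_id, particles$particle_id)
  if (length(missing_eds) || length(extra_eds))
    stop("particle/EDS id mismatch; particles without EDS: [",
         paste(missing_eds, collapse = ", "), "]; EDS without particle: [",
         paste(extra_eds, collapse = ", "), "]")
  if (anyDuplicated(eds$particle_id))
    stop("duplicated particle_id in EDS table")
  m <- match(particles$particle_id, eds$particle_id)
  res <- lapply(seq_len(nrow(particles)), function(i) {
    row <- eds[m[i], , drop = FALSE]
    raw <- unlist(row[intersect(EDS_ELEMENTS, names(row))])
    at <- if ("acquisition_time_s" %in% names(row)) row$acquisition_time_s else 10
    classify_particle(particles$is_fiber[i], renormalize(raw, at), rules)
  })
  particles$label <- vapply(res, `[[`, character(1), "label")
  particles$tsi <- vapply(res, `[[`, numeric(1), "tsi")
  particles$rule_trace <- vapply(res, function(r)
    paste(r$rule_trace, collapse = ";"), character(1))
  particles
}

#' Per-class summary of extra-framework cations
#'
#' Mean and standard deviation of the Mg, Na, K, Ca mass percentages within
#' each class label — the compositional clustering view used to check that
#' erionite-like particles share consistent cation ratios.
#'
#' @param comps List of `"eds_composition"` objects (or a data frame with
#'   element columns).
#' @param labels Character vector of class labels, one per composition.
#' @return Data frame with one row per (label, element): columns `label`,
#'   `element`, `mean_pct`, `sd_pct`, `n`.
#' @export
cation_profile <- function(comps, labels) {
  if (length(labels) == 0L) stop("no labeled compositions")
  cations <- c("Mg", "Na", "K", "Ca")
  if (is.data.frame(comps)) {
    mat <- as.matrix(comps[, cations, drop = FALSE])
  } else {
    if (length(comps) != length(labels))
      stop("'comps' and 'labels' must have equal length")
    mat <- t(vapply(comps, function(cp) {
      v <- if (inherits(cp, "eds_composition")) cp$mass_pct else cp
      v[cations]
    }, numeric(length(cations))))
    colnames(mat) <- cations
  }
  if (nrow(mat) != length(labels)) stop("'comps' and 'labels' must match")
  out <- do.call(rbind, lapply(split(seq_along(labels), labels), function(ix) {
    data.frame(label = labels[ix[1]], element = cations,
               mean_pct = colMeans(mat[ix, , drop = FALSE]),
               sd_pct = apply(mat[ix, , drop = FALSE], 2, stats::sd),
               n = length(ix), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$sd_pct[is.na(out$sd_pct)] <- 0
  out
}
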