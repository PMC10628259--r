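# Scenario definitions and end-to-end orchestration: build feature layers
# and weights per scenario, prioritize, select the top fraction, evaluate
# every scenario against the full species pool, compute trade-offs against
# the reference scenario, and compare scenarios spatially.

#' The default set of 13 expansion scenarios
#'
#' One national scenario (all species, kingdom-balanced weights), one
#' transnational scenario (species weighted by their endemism share), two
#' regional-coordination scenarios (independent prioritizations within
#' political or ecological subregions), five taxon scenarios (birds,
#' mammals, amphibians & reptiles, plants, butterflies), two at-risk
#' scenarios (national and global assessment schemes), and two facet
#' scenarios (functional and phylogenetic distinctiveness weights).
#'
#' @return A tibble with columns `name`, `filter_type` (`all`/`group`/
#'   `status`), `filter_value`, `weight_source` (`uniform`/`endemism`/`fd`/
#'   `pd`), `coordination` (`national`/`political`/`ecological`).
#' @export
default_scenarios <- function() {
  tibble::tribble(
    ~name,                  ~filter_type, ~filter_value, ~weight_source, ~coordination,
    "national",             "all",        NA,            "uniform",      "national",
    "transnational",        "all",        NA,            "endemism",     "national",
    "provinces_territories","all",        NA,            "uniform",      "political",
    "ecozones",             "all",        NA,            "uniform",      "ecological",
    "birds",                "group",      "bird",        "uniform",      "national",
    "mammals",              "group",      "mammal",      "uniform",      "national",
    "amphibians_reptiles",  "group",      "amphibian_reptile", "uniform", "national",
    "plants",               "group",      "plant",       "uniform",      "national",
    "butterflies",          "group",      "butterfly",   "uniform",      "national",
    "national_at_risk",     "status",     "national",    "uniform",      "national",
    "global_at_risk",       "status",     "global",      "uniform",      "national",
    "functional",           "all",        NA,            "fd",           "national",
    "phylogenetic",         "all",        NA,            "pd",           "national"
  )
}

# species weights for one scenario row; returns tibble(species_id, kingdom, w)
scenario_weights <- function(spec_row, species, fd = NULL, pd = NULL) {
  base <- tibble::tibble(species_id = species$species_id,
                         kingdom = species$kingdom,
                         group = species$group,
                         status_national = species$status_national,
                         status_global = species$status_global,
                         w = 1)
  base$w <- switch(
    spec_row$weight_source,
    uniform = rep(1, nrow(base)),
    endemism = species$endemism_share,
    fd = fd$fd_contribution[match(base$species_id, fd$species_id)],
    pd = pd$pd_contribution[match(base$species_id, pd$species_id)],
    abort(sprintf("unknown weight source '%s'", spec_row$weight_source))
  )
  out <- switch(
    spec_row$filter_type,
    all = base,
    group = {
      sub <- base[base$group == spec_row$filter_value, ]
      if (nrow(sub) == 0) abort(sprintf("no species in group '%s'",
                                        spec_row$filter_value))
      sub
    },
    status = subset_by_status(base, scheme = spec_row$filter_value),
    abort(sprintf("unknown filter type '%s'", spec_row$filter_type))
  )
  kingdom_balance(out[c("species_id", "kingdom", "w")])
}

#' Run the full scenario suite on a landscape
#'
#' End-to-end pipeline: builds the climate win-win feature layers, the mask
#' (protected / free / excluded), per-scenario weights (kingdom-balanced,
#' with endemism, at-risk, functional- and phylogenetic-distinctiveness
#' variants), ranks land per scenario at its coordination scale, selects the
#' top `protect_fraction` of cells, evaluates every selection against the
#' *full* species pool with the Species Protection Index and
#' weighted-endemism capture, computes trade-offs against the reference
#' scenario, and compares scenarios (overlap classes, rank correlations,
#' ordination).
#'
#' @param landscape A [generate_landscape()] result (or a compatible list).
#' @param scenarios Scenario table as from [default_scenarios()].
#' @param protect_fraction Fraction of land each scenario protects.
#'   Default 0.30.
#' @param winwin_coeffs Coefficients for [winwin_combine()].
#' @param rule Marginal-loss rule. Default `"caz"`.
#' @param reference Name of the reference scenario for trade-offs.
#'   Default `"national"`.
#' @param protected_threshold,hfi_threshold Mask thresholds (defaults 0.43
#'   and 10).
#' @param evaluate_on `"current"` (default) evaluates protection on the
#'   current-climate stack; `"winwin"` evaluates on the combined layers.
#' @param compare Logical: run the cross-scenario comparison stage (the
#'   ordination needs at least 4 scenarios). Default `TRUE`.
#' @param seed Seed for the ordination and any random tie-breaks.
#' @return An object of class `scenario_suite`: list with `scenarios`,
#'   `ranks`, `selections`, `reports`, `summary` (per-scenario tibble with
#'   SPI, capture and trade-offs), `by_group` (per-scenario per-group
#'   trade-offs), `overlap`, `correlations`, `ordination`, `baseline`
#'   (existing-protection report), and `manifest`.
#' @export
run_suite <- function(landscape, scenarios = default_scenarios(),
                      protect_fraction = 0.30,
                      winwin_coeffs = c(both = 0.5, now = 0.35, fut = 0.15),
                      rule = "caz", reference = "national",
                      protected_threshold = 0.43, hfi_threshold = 10,
                      evaluate_on = c("current", "winwin"),
                      compare = TRUE, seed = 1L) {
  evaluate_on <- match.arg(evaluate_on)
  stopifnot(reference %in% scenarios$name)
  species <- landscape$species

  stage <- function(name, scenario, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for scenario '%s': %s",
                    name, scenario, conditionMessage(e)))
    })
  }

  mask <- coverage_to_class(landscape$coverage, landscape$hfi,
                            landscape$excluded,
                            protected_threshold = protected_threshold,
                            hfi_threshold = hfi_threshold)
  domain <- which(mask$class != MASK_EXCLUDED)
  features <- winwin_combine(landscape$suitability_current,
                             landscape$suitability_future,
                             coeffs = winwin_coeffs)

  fd <- pd <- NULL
  if ("fd" %in% scenarios$weight_source) {
    fd <- stage("weights", "functional",
                functional_distinctiveness(landscape$traits))
  }
  if ("pd" %in% scenarios$weight_source) {
    pd <- stage("weights", "phylogenetic",
                phylogenetic_distinctiveness(landscape$tree, species))
  }

  eval_stack <- if (evaluate_on == "current") {
    landscape$suitability_current
  } else {
    features
  }
  R_all <- range_size(eval_stack, domain)
  if (any(R_all == 0)) {
    warn(sprintf(
      "%d species have no range in the evaluation domain and are dropped",
      sum(R_all == 0)))
    eval_stack <- eval_stack[, R_all > 0, drop = FALSE]
    species <- species[R_all > 0, , drop = FALSE]
    R_all <- R_all[R_all > 0]
  }
  targets <- spi_targets(R_all)
  we <- weighted_endemism(eval_stack, domain)
  at_risk <- species$status_national %in% at_risk_statuses$national
  we_risk <- if (any(at_risk)) {
    weighted_endemism(eval_stack[, at_risk, drop = FALSE], domain)
  } else NULL

  ranks <- list(); selections <- list(); reports <- list()
  for (i in seq_len(nrow(scenarios))) {
    srow <- scenarios[i, ]
    nm <- srow$name
    w_tbl <- stage("weights", nm, scenario_weights(srow, species, fd, pd))
    feat_s <- features[, w_tbl$species_id, drop = FALSE]
    w <- w_tbl$w

    rk <- stage("prioritize", nm, {
      if (srow$coordination == "national") {
        greedy_rank(feat_s, w, mask, rule = rule)
      } else {
        subs <- if (srow$coordination == "political") {
          landscape$subregions_political
        } else {
          landscape$subregions_ecological
        }
        subregion_rank(feat_s, w, mask, subs, rule = rule)
      }
    })
    sel <- stage("select", nm,
                 suppressWarnings(top_fraction(rk, protect_fraction)))
    rep_s <- stage("evaluate", nm,
                   suppressWarnings(
                     assess_protection(eval_stack, sel, targets,
                                       species = species, domain = domain)))
    ranks[[nm]] <- rk; selections[[nm]] <- sel; reports[[nm]] <- rep_s
  }

  ref_rep <- reports[[reference]]
  summary <- purrr::imap(reports, function(rp, nm) {
    tibble::tibble(
      scenario = nm,
      n_protected = rp$n_protected,
      spi = rp$spi,
      capture = biodiversity_capture(we, selections[[nm]], ncol(eval_stack)),
      capture_at_risk = if (is.null(we_risk)) NA_real_ else
        biodiversity_capture(we_risk, selections[[nm]], sum(at_risk)),
      fd_protected = if (is.null(fd)) NA_real_ else
        facet_tradeoff(rp$species$protected,
                       fd$fd_contribution[match(rp$species$species_id,
                                                fd$species_id)]),
      pd_protected = if (is.null(pd)) NA_real_ else
        facet_tradeoff(rp$species$protected,
                       pd$pd_contribution[match(rp$species$species_id,
                                                pd$species_id)])
    )
  }) |> dplyr::bind_rows()
  summary <- dplyr::bind_cols(
    summary,
    tradeoff(summary$n_protected, ref_rep$n_protected)
  )

  by_group <- purrr::imap(reports, function(rp, nm) {
    ref <- ref_rep$by_group |>
      dplyr::select("grouping", "level", ref_protected = "n_protected")
    rp$by_group |>
      dplyr::mutate(scenario = nm, .before = 1) |>
      dplyr::left_join(ref, by = c("grouping", "level")) |>
      dplyr::mutate(tradeoff = ifelse(.data$ref_protected > 0,
                                      100 * .data$n_protected /
                                        .data$ref_protected - 100, NA_real_))
  }) |> dplyr::bind_rows()

  overlap <- correlations <- ordination <- NULL
  if (compare && length(selections) >= 2) {
    overlap <- overlap_classes(selections, mask, we = we,
                               we_at_risk = we_risk,
                               n_species = ncol(eval_stack),
                               n_species_at_risk = sum(at_risk))
    correlations <- pairwise_correlation(ranks)
    if (length(selections) >= 4) {
      ordination <- ordinate_scenarios(selections, k = 2, seed = seed)
    }
  }

  baseline <- existing_protection_report(landscape, mask,
                                         eval_stack = eval_stack,
                                         targets = targets, domain = domain)

  structure(
    list(scenarios = scenarios, mask = mask, ranks = ranks,
         selections = selections, reports = reports, summary = summary,
         by_group = by_group, overlap = overlap, correlations = correlations,
         ordination = ordination, baseline = baseline,
         manifest = list(
           protect_fraction = protect_fraction,
           winwin_coeffs = winwin_coeffs, rule = rule,
           reference = reference,
           protected_threshold = protected_threshold,
           hfi_threshold = hfi_threshold,
           evaluate_on = evaluate_on, seed = seed,
           n_scenarios = nrow(scenarios),
           n_species = ncol(eval_stack),
           n_cells_domain = length(domain),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "scenario_suite"
  )
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat(sprintf("<scenario_suite> %d scenarios at %.0f%% protection, rule '%s'\n",
              nrow(x$scenarios), 100 * x$manifest$protect_fraction,
              x$manifest$rule))
  print(x$summary[c("scenario", "n_protected", "spi", "capture", "tradeoff")],
        n = nrow(x$summary))
  invisible(x)
}

#' Evaluate what existing protected areas already achieve
#'
#' Scores the protected-cells-only "selection" with the Species Protection
#' Index machinery — the baseline any expansion scenario is compared
#' against.
#'
#' @param landscape A landscape (for its suitability stack and species).
#' @param mask A `mask_stack`.
#' @param eval_stack,targets,domain Optional precomputed pieces (stack,
#'   targets, evaluation domain); derived from the landscape when missing.
#' @return A `protection_report`.
#' @export
existing_protection_report <- function(landscape, mask, eval_stack = NULL,
                                       targets = NULL, domain = NULL) {
  eval_stack <- eval_stack %||% landscape$suitability_current
  domain <- domain %||% which(mask$class != MASK_EXCLUDED)
  targets <- targets %||% spi_targets(range_size(eval_stack, domain))
  sel <- mask$class == MASK_PROTECTED
  if (!any(sel)) warn("no protected cells: baseline SPI is 0")
  suppressWarnings(
    assess_protection(eval_stack, sel, targets,
                      species = landscape$species, domain = domain))
}
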