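# End-to-end study pipeline: ingest -> match -> exclude -> normalize ->
# classify -> score -> fit -> adjust -> report, behind one config. Every
# exclusion is logged, every table reconciles with the exclusion flow, and a
# rerun with the same config and seed reproduces byte-identical tables.

#' Study configuration
#'
#' @param input_y1,input_y2 CSV paths for the two database years, or NULL to
#'   simulate.
#' @param simulate a [supply_config()] used when inputs are NULL.
#' @param dv_path,npsc_path optional overrides for the DV and NPSC table
#'   files.
#' @param classifier_mode `"percent_of_dv"` (default) or
#'   `"relative_to_baseline"`.
#' @param min_group_n minimum reformulation-group size kept in models.
#' @param min_cell_n minimum cell size for per-category FSANZ models.
#' @param out_dir output directory (created on run).
#' @param seed integer seed controlling simulation.
#' @return list of class `study_config`.
#' @export
study_config <- function(input_y1 = NULL, input_y2 = NULL,
                         simulate = supply_config(),
                         dv_path = NULL, npsc_path = NULL,
                         classifier_mode = "percent_of_dv",
                         min_group_n = 5, min_cell_n = 10,
                         out_dir = tempfile("study"), seed = 1L) {
  stopifnot(min_group_n >= 1, min_cell_n >= 1)
  for (p in c(input_y1, input_y2, dv_path, npsc_path))
    if (!is.null(p) && !file.exists(p))
      stop("configured file does not exist: ", p, call. = FALSE)
  cfg <- list(input_y1 = input_y1, input_y2 = input_y2, simulate = simulate,
              dv_path = dv_path, npsc_path = npsc_path,
              classifier_mode = classifier_mode,
              min_group_n = min_group_n, min_cell_n = min_cell_n,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

config_hash <- function(config) {
  strip <- config[setdiff(names(config), "out_dir")]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(strip, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full reformulation-price study
#'
#' Executes the cascade in the study's order: match on (product code,
#' retailer, container size); drop TRA W/X; drop invalid prices (price
#' analysis set); drop incomplete nutrition (reformulation set); classify the
#' seven core nutrients into the five DV-threshold groups; fit the
#' reformulation-price mixed models with BH adjustment across all group terms
#' (one family); drop FSANZ-ineligible pairs, score both years with the NPSC
#' and fit FSANZ-change models overall and per TRA category (BH across
#' category cells). Writes every table as CSV plus a machine-readable
#' summary, and logs each stage.
#'
#' @param config a [study_config()].
#' @param write logical; write CSV outputs to `config$out_dir`.
#' @param quiet suppress console stage logging.
#' @return list of class `study_report` (tables + provenance).
#' @export
run_study <- function(config, write = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message("[reformprice] ", ...)
  dv <- default_dv_table(config$dv_path)
  npsc <- load_npsc_tables(config$npsc_path)

  if (!is.null(config$input_y1)) {
    db1 <- read_food_db(config$input_y1)
    db2 <- read_food_db(config$input_y2)
    truth <- NULL
  } else {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- generate_supply(sim_cfg)
    db1 <- sim$db1; db2 <- sim$db2; truth <- sim$truth
  }
  say("year 1: ", nrow(db1$records), " records; year 2: ",
      nrow(db2$records), " records")
  val1 <- validate_db(db1); val2 <- validate_db(db2)

  pairs <- match_products(db1, db2)
  say("matched pairs: ", nrow(pairs))
  pairs <- apply_exclusions(pairs, "category_WX")
  price_pairs <- apply_exclusions(pairs, "invalid_price")
  say("price analysis set: ", nrow(price_pairs))
  price_overall <- summarize_prices(price_pairs, "overall")
  price_by_cat <- summarize_prices(price_pairs, "tra_category")
  price_by_ret <- summarize_prices(price_pairs, "retailer_id")

  reform_pairs <- apply_exclusions(price_pairs, "incomplete_nutrition")
  say("reformulation set: ", nrow(reform_pairs))
  classified <- classify_pairs(reform_pairs, dv, config$classifier_mode)
  groups_overall <- tabulate_groups(classified, "overall")
  groups_by_cat <- tabulate_groups(classified, "tra_category")

  chi <- do.call(rbind, lapply(CORE_NUTRIENTS, function(nu) {
    tab <- brand_group_contingency(classified, nu)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    res <- if (nrow(tab) >= 2 && all(colSums(tab) > 0))
      chi_square(tab) else list(statistic = NA_real_, df = NA_integer_,
                                p.value = NA_real_, caution = TRUE)
    data.frame(nutrient = nu, statistic = res$statistic, df = res$df,
               p_raw = res$p.value, caution = res$caution,
               stringsAsFactors = FALSE)
  }))
  chi$p_adj <- bh_adjust(chi$p_raw)

  reform_models <- do.call(rbind, lapply(CORE_NUTRIENTS, function(nu) {
    m <- fit_reformulation_model(classified, nu, config$min_group_n)
    if (nrow(m) > 0L) m$nutrient <- nu
    m
  }))
  if (!is.null(reform_models) && nrow(reform_models) > 0L)
    reform_models$p_adj <- bh_adjust(reform_models$p_raw)

  fsanz_pairs <- apply_exclusions(reform_pairs, "fsanz_ineligible")
  say("FSANZ set: ", nrow(fsanz_pairs))
  scored <- fsanz_score_pairs(fsanz_pairs, npsc)
  fsanz_dist <- fsanz_distribution(scored)
  fsanz_overall <- fit_fsanz_model(scored, "overall", config$min_cell_n)
  fsanz_by_cat <- fit_fsanz_model(scored, "tra_category", config$min_cell_n)
  # one BH family across all FSANZ-slope cells (overall + categories);
  # the reformulation-group terms form their own family above
  fs_all_p <- c(fsanz_overall$p_raw, fsanz_by_cat$p_raw)
  if (length(fs_all_p) > 0L) {
    fs_adj <- bh_adjust(fs_all_p)
    if (nrow(fsanz_overall) > 0L)
      fsanz_overall$p_adj <- fs_adj[seq_len(nrow(fsanz_overall))]
    if (nrow(fsanz_by_cat) > 0L)
      fsanz_by_cat$p_adj <- fs_adj[nrow(fsanz_overall) + seq_len(nrow(fsanz_by_cat))]
  }

  report <- list(
    exclusion_flow = exclusion_log(fsanz_pairs),
    validation = list(y1 = val1, y2 = val2),
    price_overall = price_overall,
    price_by_category = price_by_cat,
    price_by_retailer = price_by_ret,
    groups_overall = groups_overall,
    groups_by_category = groups_by_cat,
    brand_chi_square = chi,
    reformulation_models = reform_models,
    fsanz_distribution = fsanz_dist,
    fsanz_model_overall = fsanz_overall,
    fsanz_model_by_category = fsanz_by_cat,
    scored_pairs = scored,
    classified = classified,
    truth = truth,
    provenance = list(config_hash = config_hash(config),
                      dv_version = attr(dv, "version"),
                      npsc_version = npsc$version,
                      seed = config$seed,
                      n_matched = nrow(pairs) +
                        sum(exclusion_log(pairs)$n_removed[
                          exclusion_log(pairs)$stage == "category_WX"]),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  class(report) <- "study_report"
  if (write) write_report(report, config$out_dir)
  report
}

fsanz_distribution <- function(scored) {
  ok <- !is.na(scored$score_y1) & !is.na(scored$score_y2)
  d <- scored[ok, , drop = FALSE]
  cells <- c(list(overall = d), split(d, d$fsanz_category, drop = TRUE))
  out <- do.call(rbind, lapply(names(cells), function(cell) {
    dc <- cells[[cell]]
    if (nrow(dc) == 0L) return(NULL)
    w <- wilcoxon_paired(dc$score_y1, dc$score_y2)
    data.frame(cell = cell, n = nrow(dc),
               mean_y1 = mean(dc$score_y1), sd_y1 = sd(dc$score_y1),
               median_y1 = median(dc$score_y1),
               mean_y2 = mean(dc$score_y2), sd_y2 = sd(dc$score_y2),
               median_y2 = median(dc$score_y2),
               pass_y1 = sum(dc$npsc_pass_y1), pass_y2 = sum(dc$npsc_pass_y2),
               p_raw = w$p.value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a study report to CSV + JSON
#'
#' One CSV per table (deterministic content for a fixed config and seed) and
#' a `provenance.json` carrying the config hash, table-file versions, seed
#' and timestamp (the timestamp is the only non-deterministic output).
#'
#' @param report a `study_report`.
#' @param out_dir output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("exclusion_flow", "price_overall", "price_by_category",
            "price_by_retailer", "groups_overall", "groups_by_category",
            "brand_chi_square", "reformulation_models",
            "fsanz_distribution", "fsanz_model_overall",
            "fsanz_model_by_category")
  for (tb in tabs) {
    x <- report[[tb]]
    if (is.null(x)) next
    utils::write.csv(as.data.frame(x), file.path(out_dir,
                                                 paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(report$scored_pairs)[
    , c("product_code", "retailer_id", "tra_category", "fsanz_category",
        "score_y1", "score_y2", "npsc_pass_y1", "npsc_pass_y2",
        "score_change", "delta_price")],
    file.path(out_dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
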