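#' @title Two-phase pipeline orchestration
#'
#' @description
#' `run_study()` executes the full discovery-confirmatory framework on an
#' in-memory study bundle (from [simulate_study] or [read_study]): per
#' outcome, (1) the association screen per evidence layer with BH control,
#' (2) colocalization for every plasma-significant feature in every layer
#' with data, (3) evidence-tier scoring with the direction-consistency flag,
#' (4) tier-gated two-sample MR with sensitivity columns.  `run_pipeline()`
#' is the file-based wrapper: it reads a validated configuration, loads the
#' TSV inputs, runs the study, and writes `tiers.tsv`, `mr.tsv`, `xwas.tsv`
#' and `summary.json` into the output directory.
#'
#' @name pipeline
NULL

#' Default analysis thresholds
#'
#' @return named list: `alpha_fdr` 0.05, `pph4` 0.75, `p_instr` 5e-8,
#'   `p_fallback` 5e-6, `clump_r2` 0.001, `clump_window_kb` 10000, coloc
#'   priors `p1`/`p2` 1e-4, `p12` 1e-5, prior SDs `sd1` 0.15, `sd2` 0.2.
#' @export
default_thresholds <- function() {
  list(alpha_fdr = 0.05, pph4 = 0.75, p_instr = 5e-8, p_fallback = 5e-6,
       clump_r2 = 0.001, clump_window_kb = 10000,
       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, sd1 = 0.15, sd2 = 0.2)
}

check_thresholds <- function(th) {
  for (k in c("alpha_fdr", "pph4")) {
    if (!is.numeric(th[[k]]) || th[[k]] <= 0 || th[[k]] >= 1)
      stop("threshold '", k, "' must lie in (0, 1)")
  }
  for (k in c("p_instr", "p_fallback", "p1", "p2", "p12")) {
    if (!is.numeric(th[[k]]) || th[[k]] <= 0 || th[[k]] > 1)
      stop("threshold '", k, "' must lie in (0, 1]")
  }
  if (th$clump_r2 <= 0 || th$clump_r2 > 1) stop("clump_r2 must lie in (0, 1]")
  if (th$clump_window_kb <= 0) stop("clump_window_kb must be positive")
  invisible(th)
}

#' Validate a YAML run configuration
#'
#' The configuration names the input files (`outcomes`: outcome -> GWAS TSV;
#' `layers`: layer -> list(weights, qtl) TSVs; `ld`: LD TSV), optional
#' `thresholds` overriding [default_thresholds], `seed` and `output_dir`.
#' Missing thresholds are filled with the defaults; unknown keys produce a
#' warning; missing files are a hard error naming the path.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return validated config list of class `ptmr_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("outcomes", "layers", "ld", "thresholds", "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("outcomes", "layers", "ld"))
    if (is.null(cfg[[k]])) stop("config is missing required key '", k, "'")

  th <- utils::modifyList(default_thresholds(),
                          if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  check_thresholds(th)
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."

  paths <- c(unlist(cfg$outcomes), unlist(cfg$layers), cfg$ld)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  structure(cfg[known], names = known, class = "ptmr_config")
}

#' Write a simulated study as the pipeline's TSV input files
#'
#' Emits one GWAS TSV per outcome, one weight TSV (long format: feature_id,
#' layer, snp_id, weight) and one QTL TSV per layer, a combined
#' (block-diagonal) LD TSV, and a ground-truth TSV; returns a ready
#' configuration list pointing at them.
#'
#' @param study `ptmr_study` object.
#' @param dir output directory (created if needed).
#' @return config list suitable for [validate_config]/[run_pipeline].
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- study$params$layers
  outcomes <- study$params$outcomes

  # block-diagonal LD over all feature windows
  all_ids <- unlist(lapply(study$features, function(f) rownames(f$ld)))
  big <- matrix(0, length(all_ids), length(all_ids),
                dimnames = list(all_ids, all_ids))
  for (f in study$features) big[rownames(f$ld), rownames(f$ld)] <- f$ld
  ld_path <- file.path(dir, "ld.tsv")
  write_ld(big, ld_path)

  layer_cfg <- list()
  for (l in layers) {
    wrows <- do.call(rbind, lapply(study$features, function(f) {
      w <- f$layers[[l]]$weights
      data.frame(feature_id = w$feature_id, layer = l, snp_id = w$snp_ids,
                 weight = w$weights, stringsAsFactors = FALSE)
    }))
    qrows <- do.call(rbind, lapply(study$features, function(f) {
      q <- f$layers[[l]]$qtl
      q$feature_id <- f$feature_id
      q
    }))
    wpath <- file.path(dir, paste0("weights_", l, ".tsv"))
    qpath <- file.path(dir, paste0("qtl_", l, ".tsv"))
    write_report(wrows, wpath)
    write_report(qrows, qpath)
    layer_cfg[[l]] <- list(weights = wpath, qtl = qpath)
  }

  outcome_cfg <- list()
  for (o in outcomes) {
    grows <- do.call(rbind, lapply(names(study$gwas[[o]]), function(fid) {
      g <- study$gwas[[o]][[fid]]
      g$feature_id <- fid
      g
    }))
    gpath <- file.path(dir, paste0("gwas_", o, ".tsv"))
    write_report(grows, gpath)
    outcome_cfg[[o]] <- gpath
  }
  write_report(study$truth, file.path(dir, "truth.tsv"))

  list(outcomes = outcome_cfg, layers = layer_cfg, ld = ld_path,
       seed = study$params$seed, output_dir = dir)
}

#' Read pipeline inputs referenced by a configuration into a study bundle
#'
#' @param config validated configuration (see [validate_config]).
#' @return `ptmr_study`-shaped list (features, gwas, params).
#' @export
read_study <- function(config) {
  if (!inherits(config, "ptmr_config")) config <- validate_config(config)
  big_ld <- read_ld(config$ld)
  layers <- names(config$layers)
  outcomes <- names(config$outcomes)

  layer_data <- lapply(layers, function(l) {
    list(weights = read_report(config$layers[[l]]$weights),
         qtl = read_sumstats(config$layers[[l]]$qtl,
                             dialect = NULL, quiet = TRUE))
  })
  names(layer_data) <- layers
  # qtl read via read_sumstats loses extra columns; re-read feature ids
  qtl_fids <- lapply(layers, function(l) {
    raw <- read_report(config$layers[[l]]$qtl)
    raw[, c("snp_id", "feature_id")]
  })
  names(qtl_fids) <- layers

  feature_ids <- unique(layer_data[[1]]$weights$feature_id)
  features <- lapply(feature_ids, function(fid) {
    per_layer <- lapply(layers, function(l) {
      wt <- layer_data[[l]]$weights
      wt <- wt[wt$feature_id == fid, , drop = FALSE]
      if (nrow(wt) == 0L) return(NULL)
      snps <- qtl_fids[[l]]$snp_id[qtl_fids[[l]]$feature_id == fid]
      q <- layer_data[[l]]$qtl
      q <- q[q$snp_id %in% snps, , drop = FALSE]
      list(weights = list(feature_id = fid, layer = l,
                          snp_ids = wt$snp_id, weights = wt$weight),
           qtl = q)
    })
    names(per_layer) <- layers
    per_layer <- per_layer[!vapply(per_layer, is.null, logical(1))]
    window <- unique(unlist(lapply(per_layer, function(x) x$qtl$snp_id)))
    window <- intersect(rownames(big_ld), window)
    list(feature_id = fid, ld = big_ld[window, window, drop = FALSE],
         layers = per_layer)
  })
  names(features) <- feature_ids

  gwas <- lapply(outcomes, function(o) {
    g <- read_sumstats(config$outcomes[[o]], quiet = TRUE)
    per_feature <- lapply(features, function(f) {
      window <- rownames(f$ld)
      g[g$snp_id %in% window, , drop = FALSE]
    })
    names(per_feature) <- feature_ids
    per_feature
  })
  names(gwas) <- outcomes

  structure(list(features = features, gwas = gwas, truth = NULL,
                 params = list(layers = layers, outcomes = outcomes,
                               n_features = length(features),
                               seed = config$seed)),
            class = "ptmr_study")
}

#' Run the two-phase analysis on a study bundle
#'
#' @param study `ptmr_study` object ([simulate_study] or [read_study]).
#' @param thresholds named list (see [default_thresholds]); partial lists
#'   are completed with the defaults.
#' @return object of class `ptmr_run`: list with `xwas` (per layer/outcome
#'   screen), `coloc` (per feature/layer PPH4 table), `tiers`, `mr`,
#'   `gated` (refused features with reasons) and `summary`.
#' @export
run_study <- function(study, thresholds = list()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  check_thresholds(th)
  layers <- study$params$layers
  outcomes <- study$params$outcomes
  plasma <- layers[[1]]

  xwas_all <- list(); coloc_all <- list(); tier_all <- list()
  mr_all <- list(); gated <- list()

  for (o in outcomes) {
    gwas_o <- study$gwas[[o]]

    screen <- lapply(layers, function(l) {
      wms <- lapply(study$features, function(f)
        if (!is.null(f$layers[[l]])) f$layers[[l]]$weights else NULL)
      wms <- wms[!vapply(wms, is.null, logical(1))]
      if (length(wms) == 0L) return(NULL)
      wms <- lapply(wms, function(w) {
        w$ld <- study$features[[w$feature_id]]$ld
        w
      })
      run_layer(wms, gwas_o, outcome = o, alpha = th$alpha_fdr)
    })
    names(screen) <- layers
    xwas_o <- do.call(rbind, screen[!vapply(screen, is.null, logical(1))])
    rownames(xwas_o) <- NULL
    xwas_all[[o]] <- xwas_o

    plasma_scr <- screen[[plasma]]
    sig_features <- plasma_scr$feature_id[plasma_scr$significant]

    coloc_rows <- list(); tier_rows <- list()
    for (fid in sig_features) {
      f <- study$features[[fid]]
      assoc <- list(); colocs <- list()
      for (l in layers) {
        if (is.null(f$layers[[l]])) next
        row <- screen[[l]][screen[[l]]$feature_id == fid, , drop = FALSE]
        if (nrow(row) == 0L || is.na(row$pvalue)) next
        assoc[[l]] <- list(p_fdr = row$p_fdr, zscore = row$zscore)
        cres <- tryCatch(
          colocalize(f$layers[[l]]$qtl, gwas_o[[fid]],
                     p1 = th$p1, p2 = th$p2, p12 = th$p12,
                     sd1 = th$sd1, sd2 = th$sd2,
                     feature_id = fid, layer = l, outcome = o),
          error = function(e) NULL)
        if (!is.null(cres)) {
          colocs[[l]] <- cres$pph4
          coloc_rows[[length(coloc_rows) + 1L]] <-
            data.frame(feature_id = fid, layer = l, outcome = o,
                       pph0 = cres$pph0, pph1 = cres$pph1, pph2 = cres$pph2,
                       pph3 = cres$pph3, pph4 = cres$pph4,
                       n_snps = cres$n_snps, stringsAsFactors = FALSE)
        }
      }
      if (length(assoc) == 0L || names(assoc)[1] != plasma) next
      tier_rows[[fid]] <- score_feature(assoc, colocs, alpha = th$alpha_fdr,
                                        pph4_threshold = th$pph4,
                                        feature_id = fid, outcome = o)
    }
    coloc_o <- if (length(coloc_rows) > 0) do.call(rbind, coloc_rows) else NULL
    tier_o <- if (length(tier_rows) > 0) {
      tr <- do.call(rbind, lapply(tier_rows, function(r) {
        r[c("feature_id", "outcome", "score", "tier", "direction_consistent")]
      }))
      rownames(tr) <- NULL
      class(tr) <- "data.frame"
      tr
    } else NULL
    coloc_all[[o]] <- coloc_o
    tier_all[[o]] <- tier_o

    if (!is.null(tier_o)) {
      for (i in seq_len(nrow(tier_o))) {
        rec <- tier_o[i, ]
        fid <- rec$feature_id
        f <- study$features[[fid]]
        res <- run_mr(rec, f$layers[[plasma]]$qtl, gwas_o[[fid]], f$ld,
                      p_primary = th$p_instr, p_fallback = th$p_fallback,
                      clump_r2 = th$clump_r2,
                      clump_window_kb = th$clump_window_kb)
        if (inherits(res, "mr_result")) {
          mr_all[[length(mr_all) + 1L]] <- as.data.frame(res)
        } else {
          res$outcome <- o
          gated[[length(gated) + 1L]] <- res
        }
      }
    }
  }

  tiers <- do.call(rbind, tier_all[!vapply(tier_all, is.null, logical(1))])
  if (!is.null(tiers)) rownames(tiers) <- NULL
  mr_df <- if (length(mr_all) > 0) do.call(rbind, mr_all) else NULL
  coloc_df <- do.call(rbind, coloc_all[!vapply(coloc_all, is.null, logical(1))])
  xwas_df <- do.call(rbind, xwas_all)
  rownames(xwas_df) <- NULL

  counts <- if (!is.null(tiers)) tier_table(tiers) else
    stats::setNames(integer(4), TIER_LEVELS)
  structure(list(
    xwas = xwas_df, coloc = coloc_df, tiers = tiers, mr = mr_df,
    gated = gated, thresholds = th,
    summary = list(
      tier_counts = as.list(counts),
      n_features_screened = length(study$features),
      n_plasma_significant = if (is.null(tiers)) 0L else
        length(unique(tiers$feature_id)),
      n_mr_estimates = if (is.null(mr_df)) 0L else nrow(mr_df),
      n_gated = length(gated),
      seed = study$params$seed)),
    class = "ptmr_run")
}

#' @export
print.ptmr_run <- function(x, ...) {
  s <- x$summary
  cat("Two-phase screen:", s$n_features_screened, "features;",
      s$n_plasma_significant, "plasma-significant\n")
  cat("  tiers:", paste(sprintf("%s %d", names(s$tier_counts),
                                unlist(s$tier_counts)), collapse = ", "), "\n")
  cat("  MR estimates:", s$n_mr_estimates, "| gated/refused:", s$n_gated, "\n")
  invisible(x)
}

#' Run the pipeline from a configuration file and write the report bundle
#'
#' @param config YAML path, plain list, or `ptmr_config`.
#' @return `ptmr_run` (invisibly); writes `xwas.tsv`, `tiers.tsv`, `mr.tsv`
#'   and `summary.json` into `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  study <- read_study(config)
  run <- run_study(study, config$thresholds)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_report(run$xwas, file.path(out, "xwas.tsv"))
  if (!is.null(run$tiers)) write_report(run$tiers, file.path(out, "tiers.tsv"))
  if (!is.null(run$mr)) write_report(run$mr, file.path(out, "mr.tsv"))
  jsonlite::write_json(run$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}
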