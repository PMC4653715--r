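# End-to-end orchestration of the analysis stages, with config handling
# and per-stage logging.

#' Read a key = value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted.  Known keys: `tps`, `tree`,
#' `covariates`, `outdir`, `k`, `retain_pcs`, `n_perm`, `n_sims`, `n_boot`,
#' `cutoff`, `seed`, `exclude` (comma-separated species codes).
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    cfg[[m[2L]]] <- if (!is.na(num)) num else val
  }
  cfg
}

.default_config <- function() {
  list(k = 100, retain_pcs = 3, n_perm = 999, n_sims = 1000, n_boot = 1000,
       cutoff = 0.9, seed = 1, exclude = "", outdir = ".")
}

.log_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] stage %-9s ...", format(Sys.time(), "%H:%M:%S"), name))
  res <- force(expr)
  message(sprintf("[%s] stage %-9s done in %.1fs",
                  format(Sys.time(), "%H:%M:%S"), name,
                  proc.time()[["elapsed"]] - t0))
  res
}

.stamp <- function(df, cfg, keys = c("seed")) {
  for (k in keys) df[[k]] <- cfg[[k]]
  df
}

#' Run the full opercle-shape analysis pipeline
#'
#' Chains the stages of the workflow over TPS / Newick / CSV inputs (or a
#' freshly simulated bundle): semilandmark resampling and Procrustes
#' alignment; shape- and form-space ordination with broken-stick
#' assessment; CVA and Procrustes ANOVA over feeding groupings; PGLS of
#' shape/size against the ecological covariates; the six-model
#' macroevolutionary comparison (a model-fit table per variable);
#' phylogenetic signal (Blomberg's K and Pagel's lambda); the pairwise
#' distance-contrast convergence test; and disparity through time with MDI.
#' Each stage writes a CSV into `outdir` (stochastic outputs embed the seed
#' and replicate counts) and logs timing to stderr.
#'
#' The analysis species set is the intersection of the species codes found
#' in the TPS, tree and covariate inputs; mismatches are reported by name
#' and dropped.
#'
#' @param config A named list or a path to a `key = value` file
#'   ([read_config()]).  Required when not simulating: `tps`, `tree`,
#'   `covariates`.  See [read_config()] for the optional keys.
#' @param stages Character vector of stages to run, in pipeline order from
#'   `"simulate"`, `"align"`, `"ordinate"`, `"cva"`, `"panova"`, `"pgls"`,
#'   `"fitmodels"`, `"signal"`, `"converge"`, `"dtt"`.  `"simulate"`
#'   generates a synthetic bundle into `outdir` and analyses it.
#' @return Invisible list of per-stage results.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("align", "ordinate", "cva", "panova",
                                    "pgls", "fitmodels", "signal",
                                    "converge", "dtt")) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  known <- c("simulate", "align", "ordinate", "cva", "panova", "pgls",
             "fitmodels", "signal", "converge", "dtt")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown subcommand(s): ", paste(bad, collapse = ", "),
         "\nusage: run_pipeline(config, stages = c(",
         paste(dQuote(known, FALSE), collapse = ", "), "))")
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  results <- list()

  if ("simulate" %in% stages) {
    ds <- .log_stage("simulate", make_synthetic_dataset(seed = as.integer(cfg$seed),
                                                        k = as.integer(cfg$k)))
    paths <- write_dataset(ds, outdir)
    cfg$tps <- paths[["tps"]]; cfg$tree <- paths[["tree"]]
    cfg$covariates <- paths[["covariates"]]
    results$simulate <- ds
  }
  for (key in c("tps", "tree", "covariates"))
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'")

  specs <- read_tps(cfg$tps)
  tree <- read_newick(cfg$tree)
  covs <- read_covariates(cfg$covariates)

  sp_tps <- unique(vapply(specs, `[[`, "", "species_code"))
  sets <- list(tps = sp_tps, tree = tree$tip.label,
               covariates = covs$species_code)
  common <- Reduce(intersect, sets)
  if (length(common) < 4L) stop("fewer than 4 species shared across inputs")
  for (nm in names(sets)) {
    dropped <- setdiff(sets[[nm]], common)
    if (length(dropped))
      message("dropping from ", nm, " (not shared by all inputs): ",
              paste(dropped, collapse = ", "))
  }
  specs <- specs[vapply(specs, `[[`, "", "species_code") %in% common]
  tree <- prune_to_taxa(tree, common)
  covs <- covs[covs$species_code %in% common, ]

  align <- NULL
  if (any(stages %in% c("align", "ordinate", "cva", "panova", "pgls",
                        "fitmodels", "signal", "converge", "dtt"))) {
    align <- .log_stage("align", {
      cfgs <- lapply(specs, resample_outline, k = as.integer(cfg$k))
      gpa(cfgs)
    })
    results$align <- align
  }
  species <- align$species_codes
  means <- species_mean_shapes(align, levels = tree$tip.label)

  ord <- .log_stage("ordinate", {
    sp <- shape_pca(align)
    fp <- form_pca(align)
    bs <- broken_stick(sp$eigenvalues[seq_len(min(10, sum(sp$eigenvalues >
                                                            1e-12)))])
    list(shape = sp, form = fp, broken_stick = bs)
  })
  results$ordinate <- ord
  if ("ordinate" %in% stages) {
    utils::write.csv(data.frame(specimen = rownames(ord$shape$scores),
                                species = species,
                                ord$shape$scores[, 1:min(10, ncol(ord$shape$scores))]),
                     file.path(outdir, "shape_scores.csv"), row.names = FALSE)
    utils::write.csv(ord$broken_stick,
                     file.path(outdir, "broken_stick.csv"), row.names = FALSE)
    utils::write.csv(data.frame(axis = seq_along(ord$shape$proportions),
                                proportion = ord$shape$proportions),
                     file.path(outdir, "shape_variance.csv"), row.names = FALSE)
  }
  # species-level mean scores for the comparative stages
  nret <- as.integer(cfg$retain_pcs)
  sp_scores <- apply(ord$shape$scores[, seq_len(max(nret, 3L)), drop = FALSE],
                     2L, function(v) tapply(v, species, mean))
  sp_scores <- sp_scores[tree$tip.label, , drop = FALSE]
  form_sp <- tapply(ord$form$scores[, 1L], species, mean)[tree$tip.label]
  cs_sp <- log(means$mean_cs)[tree$tip.label]
  variables <- cbind(sp_scores[, 1:3, drop = FALSE], formPC1 = form_sp,
                     lnCS = cs_sp)
  colnames(variables)[1:3] <- c("PC1", "PC2", "PC3")

  grp <- function(col) {
    g <- covs[[col]][match(tree$tip.label, covs$species_code)]
    stats::setNames(g, tree$tip.label)
  }
  if ("cva" %in% stages) {
    results$cva <- .log_stage("cva", {
      out <- list()
      for (col in c("feeding_preference", "feeding_mode")) {
        if (is.null(covs[[col]])) next
        fit <- cva(means$shapes, grp(col))
        out[[col]] <- fit
        utils::write.csv(.stamp(data.frame(species = rownames(fit$scores),
                                           group = as.character(fit$groups),
                                           fit$scores), cfg),
                         file.path(outdir, paste0("cva_", col, ".csv")),
                         row.names = FALSE)
      }
      out
    })
  }
  if ("panova" %in% stages) {
    results$panova <- .log_stage("panova", {
      rows <- list()
      for (col in c("feeding_preference", "feeding_mode")) {
        if (is.null(covs[[col]])) next
        fac <- covs[[col]][match(species, covs$species_code)]
        for (what in c("shape", "size")) {
          x <- if (what == "shape") align else
            matrix(log(align$centroid_sizes), ncol = 1L)
          fit <- procrustes_anova(x, fac, n_perm = as.integer(cfg$n_perm),
                                  seed = as.integer(cfg$seed))
          rows[[paste(col, what)]] <-
            data.frame(grouping = col, trait = what, F = fit$F,
                       df1 = fit$df[1L], df2 = fit$df[2L],
                       p_value = fit$p_value, n_perm = fit$n_perm)
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(.stamp(tab, cfg),
                       file.path(outdir, "procrustes_anova.csv"),
                       row.names = FALSE)
      tab
    })
  }
  if ("pgls" %in% stages) {
    results$pgls <- .log_stage("pgls", {
      rows <- list()
      for (v in colnames(variables)) {
        for (cv in intersect(.cov_numeric, names(covs))) {
          x <- stats::setNames(covs[[cv]], covs$species_code)
          fit <- tryCatch(pgls_fit(variables[, v], x, tree),
                          error = function(e) NULL)
          if (is.null(fit)) next
          rows[[paste(v, cv)]] <- data.frame(
            response = v, covariate = cv, n = fit$n_used,
            beta = fit$beta[2L], correlation = fit$correlation,
            t = fit$t_stat[2L], p_value = fit$p_value[2L])
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(outdir, "pgls.csv"), row.names = FALSE)
      tab
    })
  }
  if ("fitmodels" %in% stages) {
    results$fitmodels <- .log_stage("fitmodels", {
      models <- c("BM", "OU", "WN", "delta", "EB", "lambda")
      rows <- list()
      for (v in c("PC1", "PC2", "PC3", "lnCS")) {
        fits <- lapply(models, function(m)
          fit_trait_model(variables[, v], tree, m))
        cmp <- compare_models(fits)
        cmp <- data.frame(variable = v, cmp)
        rows[[v]] <- cmp
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(outdir, "model_comparison.csv"),
                       row.names = FALSE)
      tab
    })
  }
  if ("signal" %in% stages) {
    results$signal <- .log_stage("signal", {
      rows <- list()
      for (v in c("PC1", "PC2", "PC3", "lnCS")) {
        kk <- blomberg_k(variables[, v], tree,
                         n_perm = as.integer(cfg$n_perm),
                         seed = as.integer(cfg$seed))
        ll <- pagel_lambda_signal(variables[, v], tree)
        rows[[v]] <- data.frame(variable = v, K = kk$K,
                                K_p = kk$p_value,
                                lambda = ll$lambda_hat,
                                lnL_lambda = ll$lnL_lambda,
                                n_perm = kk$n_perm)
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(.stamp(tab, cfg), file.path(outdir, "signal.csv"),
                       row.names = FALSE)
      tab
    })
  }
  if ("converge" %in% stages) {
    results$converge <- .log_stage("converge", {
      excl <- if (nzchar(cfg$exclude))
        trimws(strsplit(cfg$exclude, ",")[[1L]]) else NULL
      dc <- distance_contrast_analysis(
        sp_scores[, seq_len(nret), drop = FALSE], tree, exclude = excl,
        n_sims = as.integer(cfg$n_sims), n_boot = as.integer(cfg$n_boot),
        seed = as.integer(cfg$seed))
      tab <- .stamp(dc$pairs, cfg)
      tab$n_sims <- dc$n_sims; tab$n_boot <- dc$n_boot
      utils::write.csv(tab, file.path(outdir, "distance_contrast.csv"),
                       row.names = FALSE)
      dc
    })
  }
  if ("dtt" %in% stages) {
    results$dtt <- .log_stage("dtt", {
      out <- list(
        shape = mdi(sp_scores[, seq_len(nret), drop = FALSE], tree,
                    n_sims = as.integer(cfg$n_sims), cutoff = cfg$cutoff,
                    seed = as.integer(cfg$seed)),
        size = mdi(cs_sp, tree, n_sims = as.integer(cfg$n_sims),
                   cutoff = cfg$cutoff, seed = as.integer(cfg$seed) + 1L))
      for (nm in names(out)) {
        d <- out[[nm]]
        utils::write.csv(.stamp(data.frame(time = d$times,
                                           observed = d$observed,
                                           sim_median = d$sim_median,
                                           lower = d$lower, upper = d$upper,
                                           MDI = d$MDI, p_value = d$p_value,
                                           n_sims = d$n_sims), cfg),
                         file.path(outdir, paste0("dtt_", nm, ".csv")),
                         row.names = FALSE)
      }
      out
    })
  }
  invisible(results)
}
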