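write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full diet-analysis pipeline and write a report bundle
#'
#' Orchestrates every stage on a validated diet table: per-group diet
#' importance summaries, SIMPER decomposition, ANOSIM, jackknifed niche
#' breadth with permutation comparisons, diet overlap, Ward clustering of
#' guild profiles, and two-group discriminant analysis. Writes TSV
#' artifacts whose column layouts mirror the classical summary tables,
#' plus a JSON manifest recording the package version, seed, configuration
#' and its hash, so a rerun with the same inputs is reproducible.
#'
#' @param x a [diet_table()].
#' @param map a [guild_map()].
#' @param out_dir output directory (created if needed).
#' @param groups the two group labels to compare; defaults to the first
#'   two present.
#' @inheritParams composition
#' @param n_perm permutations for ANOSIM and the diversity tests (>= 99).
#' @param log_base logarithm base for Shannon-based indices.
#' @param seed integer seed for all stochastic stages.
#' @param scale row scaling for Bray-Curtis/SIMPER.
#' @param verbose log per-stage wall time.
#' @return invisibly, a list with every stage result and the artifact
#'   paths.
#' @export
run_pipeline <- function(x, map, out_dir, groups = NULL,
                         basis = c("per_fish", "pooled"), n_perm = 9999,
                         log_base = exp(1), seed = 1,
                         scale = c("proportions", "raw"), verbose = TRUE) {
  basis <- match.arg(basis)
  scale <- match.arg(scale)
  stopifnot(inherits(x, "diet_table"), inherits(map, "guild_map"))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (is.null(groups)) groups <- unique(as.character(x$group))
  if (length(groups) < 2) {
    stop("pipeline stage 'anosim': need two groups, found only '",
         paste(groups, collapse = ", "), "'", call. = FALSE)
  }
  groups <- groups[1:2]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  results <- list()
  paths <- character()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    if (verbose) message(sprintf("[%s] done in %.2fs", name,
                                 proc.time()[["elapsed"]] - t0))
    res
  }

  results$diet_summary <- stage("diet_summary", function() {
    lapply(setNames(groups, groups), function(g) {
      tab <- diet_summary(x, g, basis = basis)
      write_tsv(tab, file.path(out_dir, sprintf("diet_summary_%s.tsv", g)))
      tab
    })
  })
  paths <- c(paths, file.path(out_dir, sprintf("diet_summary_%s.tsv", groups)))

  results$simper <- stage("simper", function() {
    tab <- simper(x, groups, scale = scale)
    write_tsv(as.data.frame(tab), file.path(out_dir, "simper.tsv"))
    tab
  })
  paths <- c(paths, file.path(out_dir, "simper.tsv"))

  results$anosim <- stage("anosim", function() {
    sub <- subset_fish(x, x$group %in% groups & !is_empty_gut(x))
    res <- anosim(bray_curtis(sub, scale = scale), sub$group, n_perm = n_perm)
    write_tsv(data.frame(r = res$statistic, p = res$p.value,
                         n_perm = res$n_perm, method = res$method,
                         seed = seed),
              file.path(out_dir, "anosim.tsv"))
    res
  })
  paths <- c(paths, file.path(out_dir, "anosim.tsv"))

  results$niche <- stage("niche", function() {
    idx <- c("s", "d", "b", "h", "ba", "j")
    rows <- lapply(idx, function(ix) {
      jk <- lapply(setNames(groups, groups), function(g) {
        jackknife(subset_fish(x, x$group == g), function(tab) {
          as.numeric(niche_breadth(composition(tab, basis = basis),
                                   log_base = log_base)[[ix]])
        })
      })
      pp <- if (ix == "s") NA_real_ else {
        diversity_permutation_test(x, index = ix, groups = groups,
                                   n_perm = n_perm, basis = basis,
                                   log_base = log_base)$p.value
      }
      data.frame(index = toupper(ix),
                 g1_mean = jk[[1]]$jack_mean, g1_se = jk[[1]]$se,
                 g2_mean = jk[[2]]$jack_mean, g2_se = jk[[2]]$se,
                 perm_p = pp, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    names(tab)[2:5] <- c(paste0(groups[1], c("_mean", "_se")),
                         paste0(groups[2], c("_mean", "_se")))
    write_tsv(tab, file.path(out_dir, "niche.tsv"))
    tab
  })
  paths <- c(paths, file.path(out_dir, "niche.tsv"))

  results$overlap <- stage("overlap", function() {
    ov <- diet_overlap(x, groups[1], groups[2], basis = basis)
    write_tsv(data.frame(index = c("schoener_alpha", "horn_ro"),
                         estimate = c(ov$schoener$estimate, ov$horn$estimate),
                         jack_mean = c(ov$schoener$jack_mean, ov$horn$jack_mean),
                         se = c(ov$schoener$se, ov$horn$se)),
              file.path(out_dir, "overlap.tsv"))
    ov
  })
  paths <- c(paths, file.path(out_dir, "overlap.tsv"))

  results$cluster <- stage("cluster", function() {
    gp <- guild_profiles(x, map, transform = "none")
    cl <- ward_two_clusters(gp$profiles, gp$labels)
    write_tsv(data.frame(fish_id = rownames(gp$profiles),
                         group = gp$labels, cluster = cl$assignment),
              file.path(out_dir, "cluster_assignment.tsv"))
    write_tsv(as.data.frame.matrix(cl$crosstab),
              file.path(out_dir, "cluster_crosstab.tsv"))
    cl
  })
  paths <- c(paths, file.path(out_dir, c("cluster_assignment.tsv",
                                         "cluster_crosstab.tsv")))

  results$dfa <- stage("dfa", function() {
    gp <- guild_profiles(x, map, transform = "arcsine")
    res <- dfa_two_group(gp$profiles, gp$labels)
    tab <- data.frame(variable = names(res$structure_corr),
                      structure_corr = res$structure_corr,
                      wilks_without = res$partial$wilks_without,
                      f_remove = res$partial$f_remove, p = res$partial$p,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr_rows <- data.frame(variable = c("(eigenvalue)", "(wilks)", "(F)",
                                         "(accuracy_pct)"),
                            structure_corr = NA, wilks_without = NA,
                            f_remove = c(res$eigenvalue, res$wilks, res$f,
                                         res$accuracy_pct),
                            p = NA)
    write_tsv(rbind(tab, attr_rows), file.path(out_dir, "dfa.tsv"))
    res
  })
  paths <- c(paths, file.path(out_dir, "dfa.tsv"))

  config <- list(groups = groups, basis = basis, n_perm = n_perm,
                 log_base = log_base, seed = seed, scale = scale,
                 n_fish = nrow(x), n_categories = length(diet_categories(x)))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "gutshift",
                   version = as.character(packageVersion("gutshift")),
                   seed = seed, config = config,
                   config_hash = md5_string(as.character(cfg_json)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, file.path(out_dir, "manifest.json"))
  invisible(c(results, list(paths = paths, config = config)))
}

# md5 of a string via a temp file (tools::md5sum is file-based)
md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
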