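# Study-shaped orchestration: guild classification, then per-group /
# per-guild diversity, NCM, NST and networks, from one validated config,
# with per-stage status and a machine-readable report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Build and validate a pipeline configuration
#'
#' @param table_path,metadata_path Input TSVs (see
#'   [read_community_table()]); alternatively pass `table`.
#' @param table A `community_table` (bypasses file input).
#' @param seed Mandatory integer seed; per-stage substreams are derived from
#'   it by stage-name hashing, so adding a stage never perturbs another
#'   stage's randomness.
#' @param niche,ncm,nst,network,diversity Per-stage option lists (see the
#'   stage functions for fields; unset fields take the stage defaults).
#' @param output_dir Where `run_pipeline` writes per-stage files (created if
#'   needed). `NULL` keeps everything in memory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(table_path = NULL, metadata_path = NULL, table = NULL,
                            seed, niche = list(), ncm = list(), nst = list(),
                            network = list(), diversity = list(),
                            output_dir = NULL) {
  if (missing(seed) || is.null(seed)) abort_arg("seed is mandatory")
  problems <- character(0)
  if (is.null(table)) {
    if (is.null(table_path) || is.null(metadata_path)) {
      problems <- c(problems, "either `table` or both `table_path` and `metadata_path` required")
    } else {
      if (!file.exists(table_path)) problems <- c(problems, sprintf("missing file: %s", table_path))
      if (!file.exists(metadata_path)) problems <- c(problems, sprintf("missing file: %s", metadata_path))
    }
  } else if (!inherits(table, "community_table")) {
    problems <- c(problems, "`table` must be a community_table")
  }
  defaults <- list(
    niche = list(n_perm = 1000, scheme = "within_sample_shuffle"),
    ncm = list(d = NULL, N = NULL),
    nst = list(metric = "ruzicka", null_algorithm = "proportional_fix", n_reps = 1000),
    network = list(n_top = 300, method = "spearman", r_threshold = 0.6,
                   p_threshold = 0.05, adjustment = "BH", min_prevalence = 0.2,
                   scope_n = 100),
    diversity = list(n_perm = 999)
  )
  merge_opts <- function(user, def, stage) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) {
      problems <<- c(problems, sprintf("unknown %s option(s): %s", stage,
                                       paste(unknown, collapse = ", ")))
    }
    utils::modifyList(def, user)
  }
  cfg <- list(table_path = table_path, metadata_path = metadata_path, table = table,
              seed = as.integer(seed),
              niche = merge_opts(niche, defaults$niche, "niche"),
              ncm = merge_opts(ncm, defaults$ncm, "ncm"),
              nst = merge_opts(nst, defaults$nst, "nst"),
              network = merge_opts(network, defaults$network, "network"),
              diversity = merge_opts(diversity, defaults$diversity, "diversity"),
              output_dir = output_dir)
  if (length(problems)) {
    abort_arg("invalid pipeline config:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(stage, msg, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full guild-resolved assembly pipeline
#'
#' Stage order: guild classification first, then the independent stages
#' (diversity, NCM, NST, networks) on the classified table. A failing stage
#' is recorded (`status = "failed"` with the condition message) and its
#' dependents skipped; independent stages still run. With the same config
#' and seed, two runs produce identical numeric outputs.
#'
#' @param config A [pipeline_config()] (or a list accepted by it).
#' @param verbose Log stage progress.
#' @return Object of class `study_report`: per-stage results/statuses plus a
#'   provenance block (config hash, seed, package version, schema version).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  t0 <- proc.time()[["elapsed"]]
  table <- if (!is.null(config$table)) config$table else
    read_community_table(config$table_path, config$metadata_path)
  groups <- unique(table$groups)
  stages <- list()
  stage_status <- function(status, reason = NULL) list(status = status, reason = reason)

  run_stage <- function(name, fun) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(list(value = fun(), status = stage_status("complete")),
                    error = function(e) list(value = NULL,
                                             status = stage_status("failed", conditionMessage(e))))
    log_stage(name, "%s (%.1fs)", out$status$status,
              proc.time()[["elapsed"]] - t1, verbose = verbose)
    out
  }

  # -- guilds -----------------------------------------------------------------
  guild_seed <- derive_seed(config$seed, "niche")
  g <- run_stage("guilds", function() {
    classify_guilds(table, n_perm = config$niche$n_perm,
                    scheme = config$niche$scheme, seed = guild_seed)
  })
  stages$guilds <- g$status
  guilds <- g$value

  # -- diversity ---------------------------------------------------------------
  dv <- run_stage("diversity", function() {
    sh <- vapply(sample_ids(table), function(s) shannon(table$counts[, s]), numeric(1L))
    per_guild <- list()
    if (!is.null(guilds)) {
      for (lab in c("generalist", "specialist")) {
        members <- guild_members(guilds, lab)
        if (length(members) >= 2L) {
          sub <- table$counts[members, , drop = FALSE]
          keep <- colSums(sub) > 0
          per_guild[[lab]] <- vapply(which(keep), function(jj) shannon(sub[, jj]), numeric(1L))
          names(per_guild[[lab]]) <- colnames(sub)[keep]
        }
      }
    }
    d <- bray_curtis(table)
    ord <- pcoa(d, n_axes = 2)
    an <- if (length(groups) >= 2L && all(table(table$groups) >= 2L)) {
      anosim(d, table$groups, n_perm = config$diversity$n_perm,
             seed = derive_seed(config$seed, "diversity"))
    } else NULL
    list(shannon = sh, shannon_by_guild = per_guild, pcoa = ord, anosim = an)
  })
  stages$diversity <- dv$status

  # -- NCM --------------------------------------------------------------------
  nc <- run_stage("ncm", function() {
    overall <- fit_ncm(table, d = config$ncm$d, N = config$ncm$N)
    strata <- if (!is.null(guilds)) {
      fit_ncm_by_guild_and_group(table, guilds, d = config$ncm$d, N = config$ncm$N)
    } else list(fits = list(), skipped = c(all = "guild stage failed"))
    list(overall = overall, strata = strata)
  })
  stages$ncm <- nc$status

  # -- NST --------------------------------------------------------------------
  ns <- run_stage("nst", function() {
    per_group <- list()
    skipped <- character(0)
    for (grp in groups) {
      g_samples <- names(table$groups)[table$groups == grp]
      if (length(g_samples) < 3L) {
        skipped[grp] <- sprintf("only %d samples (need >= 3)", length(g_samples))
        next
      }
      sub <- subset_table(table, samples = g_samples)
      per_group[[grp]] <- compute_nst(sub, metric = config$nst$metric,
                                      algorithm = config$nst$null_algorithm,
                                      n_reps = config$nst$n_reps,
                                      seed = derive_seed(config$seed, paste0("nst:", grp)),
                                      group = grp)
    }
    strata <- if (!is.null(guilds)) {
      compute_nst_by_guild_and_group(table, guilds, metric = config$nst$metric,
                                     algorithm = config$nst$null_algorithm,
                                     n_reps = config$nst$n_reps,
                                     seed = derive_seed(config$seed, "nst:strata"))
    } else list(results = list(), skipped = c(all = "guild stage failed"))
    list(per_group = per_group, skipped = skipped, strata = strata)
  })
  stages$nst <- ns$status

  # -- networks ---------------------------------------------------------------
  nw <- run_stage("network", function() {
    nets <- list(); tops <- list(); etypes <- list(); skipped <- character(0)
    for (grp in groups) {
      g_samples <- names(table$groups)[table$groups == grp]
      if (length(g_samples) < 5L) {
        skipped[grp] <- sprintf("only %d samples (need >= 5)", length(g_samples))
        next
      }
      sub <- subset_table(table, samples = g_samples)
      net <- build_network(sub, n_top = config$network$n_top,
                           method = config$network$method,
                           r_threshold = config$network$r_threshold,
                           p_threshold = config$network$p_threshold,
                           adjustment = config$network$adjustment,
                           min_prevalence = config$network$min_prevalence)
      nets[[grp]] <- net
      tops[[grp]] <- topology(net)
      if (!is.null(guilds)) {
        et <- tryCatch(edge_type_proportions(net, guilds, config$network$scope_n),
                       error = function(e) conditionMessage(e))
        if (is.character(et)) skipped[paste0(grp, ":edge_types")] <- et
        else etypes[[grp]] <- et
      }
    }
    list(networks = nets, topology = tops, edge_types = etypes, skipped = skipped)
  })
  stages$network <- nw$status

  provenance <- list(schema_version = REPORT_SCHEMA_VERSION,
                     seed = config$seed,
                     config_hash = object_hash(unclass(
                       config[setdiff(names(config), c("table", "output_dir"))])),
                     package_version = as.character(utils::packageVersion("assemblage")),
                     elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  report <- structure(list(
    guilds = guilds,
    diversity = dv$value,
    ncm = nc$value,
    nst = ns$value,
    network = nw$value,
    stages = stages,
    groups = groups,
    sample_groups = table$groups,
    provenance = provenance
  ), class = "study_report")

  if (!is.null(config$output_dir)) write_report_files(report, config$output_dir)
  report
}

write_report_files <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$guilds)) {
    write_results(report$guilds, file.path(dir, "guilds.tsv"), "TSV")
    write_results(report$guilds, file.path(dir, "guilds.json"), "JSON")
  }
  if (!is.null(report$diversity)) {
    sh <- data.frame(sample_id = names(report$diversity$shannon),
                     shannon = unname(report$diversity$shannon))
    utils::write.table(sh, file.path(dir, "shannon.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    co <- report$diversity$pcoa$coordinates
    utils::write.table(data.frame(sample_id = rownames(co), co),
                       file.path(dir, "pcoa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$ncm)) {
    write_results(report$ncm$overall, file.path(dir, "ncm_overall.json"), "JSON")
  }
  if (!is.null(report$nst)) {
    for (grp in names(report$nst$per_group)) {
      write_results(report$nst$per_group[[grp]],
                    file.path(dir, sprintf("nst_%s.json", grp)), "JSON")
    }
  }
  if (!is.null(report$network)) {
    for (grp in names(report$network$networks)) {
      write_results(report$network$networks[[grp]],
                    file.path(dir, sprintf("network_%s_edges.tsv", grp)), "TSV")
      write_graphml(report$network$networks[[grp]],
                    file.path(dir, sprintf("network_%s.graphml", grp)))
      write_results(report$network$topology[[grp]],
                    file.path(dir, sprintf("topology_%s.json", grp)), "JSON")
    }
  }
  report_light <- report
  report_light$network$networks <- NULL
  jsonlite::write_json(serialize_report(report_light), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(dir)
}

serialize_report <- function(x) {
  if (inherits(x, "ncm_fit") || inherits(x, "nst_result") ||
      inherits(x, "topology_metrics") || inherits(x, "edge_type_proportions") ||
      inherits(x, "ordination_result") || inherits(x, "anosim_result")) {
    return(unclass(x))
  }
  if (inherits(x, "guild_classification")) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, serialize_report))
  x
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  cat(sprintf("  seed %d, config %s, %.1fs\n", x$provenance$seed,
              x$provenance$config_hash, x$provenance$elapsed_s))
  invisible(x)
}

#' Tidy group-contrast table from a study report
#'
#' One row per (metric, group[, guild]) with the value and the within-metric
#' rank (1 = largest). Metrics: mean Shannon, NCM migration rate m and R^2
#' per stratum, NST per group and stratum, and the per-group network
#' topology metrics and specialist-specialist edge fraction. No hypothesis
#' tests beyond the ANOSIM already in the report.
#'
#' @param report A [run_pipeline()] result with >= 2 groups.
#' @return Data frame with columns `metric`, `group`, `guild`, `value`,
#'   `rank`, plus a logical `stochastic` flag (`value > 0.5`) for NST rows.
#' @export
compare_groups <- function(report) {
  stopifnot(inherits(report, "study_report"))
  if (length(report$groups) < 2L) abort_arg("compare_groups needs >= 2 groups")
  rows <- list()
  add <- function(metric, group, value, guild = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, group = group,
                                             guild = guild, value = value,
                                             stringsAsFactors = FALSE)
  }
  groups <- report$groups
  if (!is.null(report$diversity)) {
    sh <- report$diversity$shannon
    for (grp in groups) {
      members <- intersect(names(sh), names(report$sample_groups)[report$sample_groups == grp])
      if (length(members) == 0L) next
      add("shannon_mean", grp, mean(sh[members]))
    }
  }
  if (!is.null(report$ncm)) {
    for (key in names(report$ncm$strata$fits)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      fit <- report$ncm$strata$fits[[key]]
      add("ncm_m", parts[1L], fit$m, parts[2L])
      add("ncm_r_squared", parts[1L], fit$r_squared, parts[2L])
    }
  }
  if (!is.null(report$nst)) {
    for (grp in names(report$nst$per_group)) {
      add("nst", grp, report$nst$per_group[[grp]]$nst_group)
    }
    for (key in names(report$nst$strata$results)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      add("nst", parts[1L], report$nst$strata$results[[key]]$nst_group, parts[2L])
    }
  }
  if (!is.null(report$network)) {
    for (grp in names(report$network$topology)) {
      tp <- report$network$topology[[grp]]
      for (mt in c("avgK", "density", "gd", "modularity", "pct_positive")) {
        add(mt, grp, tp[[mt]])
      }
    }
    for (grp in names(report$network$edge_types)) {
      add("ss_fraction", grp, report$network$edge_types[[grp]]$ss)
    }
  }
  out <- do.call(rbind, rows)
  strat <- paste(out$metric, ifelse(is.na(out$guild), "", out$guild))
  out$rank <- stats::ave(-out$value, strat,
                         FUN = function(v) rank(v, ties.method = "min"))
  out$stochastic <- ifelse(out$metric == "nst", out$value > 0.5, NA)
  out
}
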