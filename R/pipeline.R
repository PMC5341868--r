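#' Default pipeline configuration
#'
#' The fully-resolved settings of a pipeline run: which stages execute, the
#' generator profile, and the parameters of every analysis stage. User YAML
#' files override these defaults key by key; anything not overridden keeps
#' the value shown here.
#'
#' @return Nested named list with entries `seed`, `outdir`, `stages`,
#'   `simulate`, `diff`, `enrich`, `network`, `assoc` and `inputs`.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "crcmirnet_run",
    stages = list(simulate = TRUE, diff = TRUE, enrich = TRUE,
                  network = TRUE, assoc = TRUE),
    simulate = list(n_mirnas = 830L, n_pairs = 6L, n_up = 40L, n_down = 8L,
                    effect_log2fc = 1.5, noise_sd = 0.3,
                    corr_strength = 0.8, adenoma_effect_frac = 0.5,
                    n_genes = 2000L, n_pathways = 50L),
    diff = list(class_a = "normal", class_b = "carcinoma",
                fc_threshold = 1.0, alpha = 0.05, adjust = "none"),
    enrich = list(p_threshold = 0.05, kappa_threshold = 0.3),
    network = list(min_abs_r = 0.7, method = "pearson",
                   correlation_class = "normal"),
    assoc = list(test = "fisher", level = 0.95),
    inputs = list(expression = NULL, metadata = NULL, targets = NULL,
                  pathways = NULL, tf = NULL, positivity = NULL)
  )
}

# Merge a user config into the defaults, recording every unknown key with a
# fuzzy-matched suggestion. Returns list(config, errors).
merge_config <- function(defaults, user, prefix = "") {
  errors <- character(0)
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      known <- names(defaults)
      d <- utils::adist(key, known, ignore.case = TRUE)
      hint <- if (length(known) && min(d) <= 3) {
        sprintf(" (did you mean '%s'?)", known[which.min(d)])
      } else ""
      errors <- c(errors, sprintf("unknown key '%s'%s", full, hint))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors <- c(errors, sprintf("'%s' must be a mapping", full))
        next
      }
      sub <- merge_config(defaults[[key]], user[[key]], full)
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, errors = errors)
}

# Field-level checks over a merged config; returns a character vector of all
# failures (empty when valid).
check_config_values <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  sim <- cfg$simulate
  chk(is_count(sim$n_mirnas) && sim$n_mirnas >= 1,
      "simulate.n_mirnas must be a positive integer")
  chk(is_count(sim$n_pairs) && sim$n_pairs >= 1,
      "simulate.n_pairs must be a positive integer")
  chk(is_count(sim$n_up) && sim$n_up >= 1,
      "simulate.n_up must be a positive integer")
  chk(is_count(sim$n_down), "simulate.n_down must be a nonnegative integer")
  chk(is.numeric(sim$noise_sd) && sim$noise_sd >= 0,
      "simulate.noise_sd must be >= 0")
  chk(is.numeric(sim$effect_log2fc) && sim$effect_log2fc >= 0,
      "simulate.effect_log2fc must be >= 0")
  chk(is.numeric(sim$corr_strength) && sim$corr_strength >= 0 &&
        sim$corr_strength < 1, "simulate.corr_strength must lie in [0, 1)")
  chk(is_count(sim$n_genes) && sim$n_genes >= 1,
      "simulate.n_genes must be a positive integer")
  chk(is_count(sim$n_pathways) && sim$n_pathways >= 1,
      "simulate.n_pathways must be a positive integer")
  chk(cfg$diff$class_a %in% tissue_classes(),
      "diff.class_a must be a known tissue class")
  chk(cfg$diff$class_b %in% tissue_classes(),
      "diff.class_b must be a known tissue class")
  chk(is.numeric(cfg$diff$fc_threshold) && cfg$diff$fc_threshold >= 0,
      "diff.fc_threshold must be >= 0")
  chk(is_prob(cfg$diff$alpha), "diff.alpha must be a probability")
  chk(cfg$diff$adjust %in% c("none", "holm", "bh"),
      "diff.adjust must be one of none, holm, bh")
  chk(is_prob(cfg$enrich$p_threshold),
      "enrich.p_threshold must be a probability")
  chk(is.numeric(cfg$enrich$kappa_threshold),
      "enrich.kappa_threshold must be numeric")
  chk(is.numeric(cfg$network$min_abs_r) && cfg$network$min_abs_r >= 0 &&
        cfg$network$min_abs_r <= 1, "network.min_abs_r must lie in [0, 1]")
  chk(cfg$network$method %in% c("pearson", "spearman"),
      "network.method must be pearson or spearman")
  chk(cfg$network$correlation_class %in% tissue_classes(),
      "network.correlation_class must be a known tissue class")
  chk(cfg$assoc$test %in% c("fisher", "chi2", "chi2_yates"),
      "assoc.test must be one of fisher, chi2, chi2_yates")
  chk(is.numeric(cfg$assoc$level) && cfg$assoc$level > 0 &&
        cfg$assoc$level < 1, "assoc.level must lie strictly in (0, 1)")
  chk(is_count(abs(cfg$seed)), "seed must be an integer")
  errs
}

#' Validate a YAML pipeline configuration
#'
#' Reads a YAML file, merges it over [default_pipeline_config()] and reports
#' *all* problems at once: unknown keys (with a closest-match suggestion) and
#' invalid field values. An empty file yields the pure defaults.
#'
#' @param path YAML file.
#' @return The fully-defaulted configuration list, or an error of class
#'   `crcmirnet_config_error` whose `errors` field lists every failure.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist", path),
          "crcmirnet_config_error")
  }
  user <- read_config_yaml(path)
  merged <- merge_config(default_pipeline_config(), user)
  errs <- c(merged$errors, check_config_values(merged$config))
  if (length(errs)) {
    abort(paste0("invalid pipeline config:\n",
                 paste0("  - ", errs, collapse = "\n")),
          "crcmirnet_config_error", errors = errs)
  }
  merged$config
}

# Which stages feed which; used to report missing prerequisites by name
# before anything runs.
check_stage_dependencies <- function(cfg) {
  st <- cfg$stages
  inp <- cfg$inputs
  errs <- character(0)
  have_expr <- isTRUE(st$simulate) ||
    (!is.null(inp$expression) && !is.null(inp$metadata))
  have_ann <- isTRUE(st$simulate) ||
    (!is.null(inp$targets) && !is.null(inp$pathways))
  have_tf <- isTRUE(st$simulate) || !is.null(inp$tf)
  if (isTRUE(st$diff) && !have_expr) {
    errs <- c(errs, "stage 'diff' needs stage 'simulate' or expression inputs")
  }
  if (isTRUE(st$enrich) && !isTRUE(st$diff)) {
    errs <- c(errs, "stage 'enrich' needs stage 'diff'")
  }
  if (isTRUE(st$enrich) && !have_ann) {
    errs <- c(errs, "stage 'enrich' needs stage 'simulate' or annotation inputs")
  }
  if (isTRUE(st$network) && !isTRUE(st$enrich)) {
    errs <- c(errs, "stage 'network' needs stage 'enrich'")
  }
  if (isTRUE(st$network) && !have_tf) {
    errs <- c(errs, "stage 'network' needs stage 'simulate' or a TF input")
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' inputs), differential calling, per-miRNA pathway enrichment, the three
#' synergy networks with hub ranking, and 2x2 association — writing every
#' stage's table to `outdir` together with the resolved configuration and a
#' structured log (stage, wall time, input file hashes). Re-running with an
#' identical configuration reproduces identical tables. A failing stage
#' aborts with a stage-named error and leaves an `INCOMPLETE` marker in the
#' run directory.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file for [validate_config()].
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) validate_config(config) else {
    merged <- merge_config(default_pipeline_config(), config)
    errs <- c(merged$errors, check_config_values(merged$config))
    if (length(errs)) {
      abort(paste0("invalid pipeline config:\n",
                   paste0("  - ", errs, collapse = "\n")),
            "crcmirnet_config_error", errors = errs)
    }
    merged$config
  }
  dep_errs <- check_stage_dependencies(cfg)
  if (length(dep_errs)) {
    abort(paste0("unsatisfied stage dependencies:\n",
                 paste0("  - ", dep_errs, collapse = "\n")),
          "crcmirnet_dependency_error")
  }
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  out_file <- function(name) file.path(cfg$outdir, name)
  write_config_yaml(cfg, out_file("config_resolved.yaml"))

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      cat("run aborted\n", file = out_file("INCOMPLETE"))
      log_line("stage=%s status=FAILED error=%s", name, conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "crcmirnet_stage_error")
    })
    log_line("stage=%s status=ok wall_s=%.2f", name,
             proc.time()[["elapsed"]] - t0)
    res
  }

  expr <- NULL; bundle <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate", function() {
      sc <- simulation_config(
        n_mirnas = cfg$simulate$n_mirnas, n_pairs = cfg$simulate$n_pairs,
        n_up = cfg$simulate$n_up, n_down = cfg$simulate$n_down,
        effect_log2fc = cfg$simulate$effect_log2fc,
        noise_sd = cfg$simulate$noise_sd,
        corr_strength = cfg$simulate$corr_strength,
        adenoma_effect_frac = cfg$simulate$adenoma_effect_frac,
        seed = cfg$seed
      )
      expr <<- simulate_expression(sc)
      bundle <<- simulate_annotations(sc, n_genes = cfg$simulate$n_genes,
                                      n_pathways = cfg$simulate$n_pathways)
      write_expression(expr, out_file("expression.tsv"),
                       out_file("metadata.tsv"))
      write_target_map(bundle$target_map, out_file("targets.tsv"))
      write_gmt(bundle$pathway_db, out_file("pathways.gmt"),
                bundle$pathway_desc)
      write_tf_map(bundle$tf_map, out_file("tf.tsv"))
      invisible(NULL)
    })
  } else if (!is.null(cfg$inputs$expression)) {
    expr <- run_stage("load", function() {
      log_line("input=%s md5=%s", cfg$inputs$expression,
               unname(tools::md5sum(cfg$inputs$expression)))
      read_expression(cfg$inputs$expression, cfg$inputs$metadata)
    })
  }
  if (is.null(bundle) && !is.null(cfg$inputs$targets)) {
    bundle <- run_stage("load_annotations", function() {
      list(target_map = read_target_map(cfg$inputs$targets),
           pathway_db = read_gmt(cfg$inputs$pathways),
           tf_map = if (!is.null(cfg$inputs$tf)) {
             read_tf_map(cfg$inputs$tf)
           })
    })
  }

  diff_table <- NULL
  if (isTRUE(cfg$stages$diff)) {
    diff_table <- run_stage("diff", function() {
      dt <- differential_mirnas(expr, cfg$diff$class_a, cfg$diff$class_b,
                                fc_threshold = cfg$diff$fc_threshold,
                                alpha = cfg$diff$alpha,
                                adjust = cfg$diff$adjust)
      write_table_tsv(dt, out_file("diff_table.tsv"))
      dt
    })
  }

  enr <- NULL
  if (isTRUE(cfg$stages$enrich)) {
    enr <- run_stage("enrich", function() {
      de <- diff_table$mirna[diff_table$call != "ns"]
      tm <- bundle$target_map[intersect(de, names(bundle$target_map))]
      if (!length(tm)) abort("no deregulated miRNA has target annotation")
      e <- enrich_mirna_targets(tm, bundle$pathway_db,
                                p_threshold = cfg$enrich$p_threshold)
      write_table_tsv(e, out_file("enrichment_table.tsv"))
      groups <- do.call(rbind, lapply(unique(e$mirna[e$enriched]),
        function(m) {
          g <- group_terms(e[e$mirna == m, ], bundle$pathway_db,
                           kappa_threshold = cfg$enrich$kappa_threshold)
          do.call(rbind, lapply(seq_along(g), function(i) {
            data.frame(mirna = m, pathway = g[[i]]$members,
                       group_id = sprintf("%s_g%02d", m, i),
                       representative = g[[i]]$representative,
                       stringsAsFactors = FALSE)
          }))
        }))
      if (!is.null(groups)) {
        write_table_tsv(groups, out_file("term_groups.tsv"))
      }
      e
    })
  }

  if (isTRUE(cfg$stages$network)) {
    run_stage("network", function() {
      de <- diff_table$mirna[diff_table$call != "ns"]
      pw_net <- pathway_synergy_network(enr)
      tf_net <- tf_synergy_network(bundle$tf_map, de)
      de_expr <- expression_matrix(
        expr$values[intersect(de, rownames(expr$values)), , drop = FALSE],
        expr$metadata)
      cor_net <- correlation_network(de_expr, cfg$network$correlation_class,
                                     method = cfg$network$method,
                                     min_abs_r = cfg$network$min_abs_r)
      write_network(pw_net, out_file("network_pathway.graphml"), "graphml")
      write_network(pw_net, out_file("network_pathway_edges.tsv"), "edgelist")
      write_network(tf_net, out_file("network_tf.graphml"), "graphml")
      write_network(cor_net, out_file("network_correlation.graphml"),
                    "graphml")
      write_table_tsv(hub_ranking(pw_net), out_file("hub_ranking.tsv"))
      invisible(NULL)
    })
  }

  if (isTRUE(cfg$stages$assoc)) {
    run_stage("assoc", function() {
      tabs <- if (!is.null(cfg$inputs$positivity)) {
        log_line("input=%s md5=%s", cfg$inputs$positivity,
                 unname(tools::md5sum(cfg$inputs$positivity)))
        df <- read.delim(cfg$inputs$positivity, stringsAsFactors = FALSE)
        out <- lapply(seq_len(nrow(df)), function(i) {
          contingency_2x2(df$a[i], df$b[i], df$c[i], df$d[i])
        })
        names(out) <- df$marker
        out
      } else {
        positivity_fixture()
      }
      res <- do.call(rbind, lapply(names(tabs), function(mk) {
        row <- associate_2x2(tabs[[mk]], level = cfg$assoc$level,
                             test = cfg$assoc$test)
        n <- row$a + row$b + row$c + row$d
        cbind(data.frame(marker = mk, stringsAsFactors = FALSE), row,
              data.frame(pct_a = percent_positive(row$a, n),
                         pct_b = percent_positive(row$b, n),
                         pct_c = percent_positive(row$c, n),
                         pct_d = percent_positive(row$d, n)))
      }))
      write_table_tsv(res, out_file("association.tsv"))
      res
    })
  }
  invisible(cfg$outdir)
}
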