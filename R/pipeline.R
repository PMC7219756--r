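#' Persist a relationship matrix as labelled TSV
#' @param G relationship matrix.
#' @param path output path.
#' @export
write_relmat <- function(G, path) {
  df <- data.frame(line = rownames(G), as.matrix(G), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by [write_relmat()]
#' @param path input path.
#' @param kind \code{"genomic"} or \code{"pedigree"} tag.
#' @export
read_relmat <- function(path, kind = "genomic") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  M <- as.matrix(df)
  structure((M + t(M)) / 2, kind = kind, bend = 0,
            class = c("relmat", "matrix", "array"))
}

default_pipeline_config <- function() {
  list(seed = 1,
       simulate = list(n_sets = 4, lines_per_set = 25, n_markers = 500),
       inputs = NULL,
       analysis = list(maf_min = 0.01, line_missing_max = 0.02,
                       founder_selfing = 9, epsilon = 1e-6,
                       validation_set = 4, spatial = TRUE))
}

stage_checksums <- function(paths) {
  ok <- file.exists(paths)
  sums <- rep(NA_character_, length(paths))
  sums[ok] <- unname(tools::md5sum(paths[ok]))
  stats::setNames(sums, basename(paths))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> relationship matrices -> univariate
#' variance-component fits and heritabilities -> forward cross-validation,
#' writing every stage's outputs plus a run manifest (config hash, input
#' checksums, package version, seed, stage timings). With
#' \code{resume = TRUE}, stages whose outputs match the checksums in the
#' existing manifest are skipped; a corrupted output forces the stage (and
#' its dependents) to re-run.
#'
#' @param config a config list or path to a YAML file. Sections:
#'   \code{seed}; \code{simulate} ([sim_config()] arguments) \emph{or}
#'   \code{inputs} (\code{genotypes}, \code{pedigree}, \code{plots} paths);
#'   \code{analysis} (\code{maf_min}, \code{line_missing_max},
#'   \code{founder_selfing}, \code{epsilon}, \code{validation_set},
#'   \code{spatial}).
#' @param out_dir output directory (created if needed).
#' @param resume skip stages already completed with matching checksums.
#' @param verbose log stage progress to stderr.
#' @return the run manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config = NULL, out_dir = "pipeline_out",
                         resume = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  cfg_text <- yaml::as.yaml(cfg)
  cfg_hash <- {
    tf <- tempfile(); writeLines(cfg_text, tf)
    unname(tools::md5sum(tf))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  if (!is.null(old) && !identical(old$config_hash, cfg_hash)) {
    say("config changed; ignoring previous manifest")
    old <- NULL
  }
  stages <- list(); outputs <- character(0)
  fresh <- FALSE  # once a stage re-runs, downstream stages re-run too
  run_stage <- function(name, out_files, fun) {
    paths <- file.path(out_dir, out_files)
    prev <- old$stages[[name]]
    if (!fresh && !is.null(prev) && all(file.exists(paths)) &&
        identical(unname(stage_checksums(paths)),
                  unname(unlist(prev$checksums)))) {
      say("stage ", name, ": up to date, skipped")
      stages[[name]] <<- prev
      outputs <<- c(outputs, paths)
      return(invisible(NULL))
    }
    fresh <<- TRUE
    say("stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    fun(paths)
    stages[[name]] <<- list(outputs = out_files,
                            checksums = as.list(stage_checksums(paths)),
                            seconds = round(proc.time()[["elapsed"]] - t0, 3))
    outputs <<- c(outputs, paths)
  }

  an <- cfg$analysis
  run_stage("data", c("genotypes.tsv", "pedigree.tsv", "plots.tsv",
                      "truth.json"), function(paths) {
    if (!is.null(cfg$inputs)) {
      file.copy(cfg$inputs$genotypes, paths[1], overwrite = TRUE)
      file.copy(cfg$inputs$pedigree, paths[2], overwrite = TRUE)
      file.copy(cfg$inputs$plots, paths[3], overwrite = TRUE)
      jsonlite::write_json(list(source = "ingested"), paths[4])
    } else {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      sim <- simulate_study(sc)
      write_genotypes(sim$genotypes, paths[1])
      write_pedigree(sim$pedigree, paths[2])
      write_plots(sim$plots, paths[3])
      jsonlite::write_json(list(vc_true = sim$truth$vc_true,
                                realized_r_g = sim$truth$realized_r_g,
                                seed = cfg$seed),
                           paths[4], auto_unbox = TRUE, digits = NA)
    }
  })

  geno <- ped <- plots <- G <- A <- NULL
  load_data <- function() {
    if (is.null(geno)) {
      geno <<- read_genotypes(file.path(out_dir, "genotypes.tsv"))
      ped <<- read_pedigree(file.path(out_dir, "pedigree.tsv"))
      plots <<- read_plots(file.path(out_dir, "plots.tsv"))
    }
  }
  run_stage("relmat", c("G.tsv", "A.tsv"), function(paths) {
    load_data()
    g <- condition_pd(build_G(mean_impute(
      qc_filter(geno, an$maf_min, an$line_missing_max))), an$epsilon)
    write_relmat(g, paths[1])
    a <- build_A_selfed(ped, an$founder_selfing)
    keep <- intersect(rownames(g), rownames(a))
    write_relmat(condition_pd(a[keep, keep], an$epsilon), paths[2])
  })
  load_relmat <- function() {
    if (is.null(G)) {
      G <<- read_relmat(file.path(out_dir, "G.tsv"))
      A <<- read_relmat(file.path(out_dir, "A.tsv"), "pedigree")
    }
  }

  run_stage("fit", c("fit.json", "genpar.tsv"), function(paths) {
    load_data(); load_relmat()
    res <- lapply(c("F5", "F6"), function(g) {
      fit <- gblup(plots, G, generation = g)
      list(fit = fit, herit = heritability(fit))
    })
    names(res) <- c("F5", "F6")
    gp <- do.call(rbind, lapply(res, `[[`, "herit"))
    utils::write.table(gp, paths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(lapply(res, function(r) list(
      vc = r$fit$fit$vc, logLik = r$fit$fit$logLik,
      converged = r$fit$fit$converged, iterations = r$fit$fit$iterations)),
      paths[1], auto_unbox = TRUE, digits = NA, dataframe = "columns")
  })

  run_stage("cv", "report.tsv", function(paths) {
    load_data(); load_relmat()
    rep_ <- compare_models(plots, G, A,
                           validation_set = an$validation_set)
    utils::write.table(rep_, paths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  manifest <- list(config_hash = cfg_hash, config = cfg,
                   package_version = as.character(utils::packageVersion("fieldgblup")),
                   seed = cfg$seed, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done; manifest at ", manifest_path)
  invisible(manifest)
}
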