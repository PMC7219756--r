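#' Configuration for the synthetic single-seed-descent study
#'
#' Defaults emulate a commercial cereal programme: four yearly crossing
#' cohorts ("sets") of ~330 SSD lines from biparental crosses among shared
#' inbred founders; an unreplicated single-location F5 observation trial per
#' set; replicated multi-location F6 trials of \code{trial_lines} lines plus
#' repeated checks over two years; genetic correlation ~0.7 between yield
#' expressed in F5 and in F6; and Table-2-scale variance components (kg per
#' plot squared) with spatially structured plot errors.
#'
#' @param n_founders,n_markers founder pool and marker panel size.
#' @param n_sets,lines_per_set crossing cohorts and SSD lines per cohort.
#' @param family_size lines advanced per biparental cross.
#' @param trial_lines,n_checks unique lines per F6 trial and check entries
#'   repeated in every trial.
#' @param replicates,years,locations F6 replicates per trial, test years and
#'   locations per year.
#' @param r_g genetic correlation between the F5 and F6 trait expressions.
#' @param sigma_g2_f5,sigma_g2_f6 genomic variances per trait.
#' @param sigma_e2_f5,sigma_e2_f6 residual plot variances per trait.
#' @param sigma_s2 spatial position-effect variance (shared form per trait:
#'   row+column for F5, 9-plot moving average for F6).
#' @param sigma_ylt2 variance of the year-location-trial effects.
#' @param mean_f5,mean_f6 yield level, kg per plot.
#' @param h2_f5,h2_f6 optional plot-heritability targets; when given,
#'   the corresponding genomic variance is solved from
#'   \code{h2 = d*sg2 / (d*sg2 + se2)} at the expected inbred G diagonal
#'   \code{d = 2 - 0.5^ssd_selfings}.
#' @param missing_rate fraction of genotype calls masked missing.
#' @param founder_selfing selfing cycles assumed for founder (parental)
#'   lines; \code{ssd_selfings} is the number of selfing rounds from F1 to
#'   the line generation.
#' @param seed integer seed; [simulate_population()] seeds with it and
#'   [simulate_trials()] with \code{seed + 1}.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founders = 80, n_markers = 2000, n_sets = 4,
                       lines_per_set = 330, family_size = 4,
                       trial_lines = 21, n_checks = 4, replicates = 2,
                       years = 2, locations = 2, r_g = 0.7,
                       sigma_g2_f5 = 0.029, sigma_g2_f6 = 0.076,
                       sigma_e2_f5 = 0.078, sigma_e2_f6 = 0.228,
                       sigma_s2 = 0.01, sigma_ylt2 = 0.25,
                       mean_f5 = 9.68, mean_f6 = 8.62,
                       h2_f5 = NULL, h2_f6 = NULL, missing_rate = 0.01,
                       founder_selfing = 9, ssd_selfings = 4, seed = NULL) {
  cfg <- as.list(environment())
  d <- 2 - 0.5^ssd_selfings
  if (!is.null(h2_f5)) cfg$sigma_g2_f5 <- h2_f5 * sigma_e2_f5 / (d * (1 - h2_f5))
  if (!is.null(h2_f6)) cfg$sigma_g2_f6 <- h2_f6 * sigma_e2_f6 / (d * (1 - h2_f6))
  stopifnot(cfg$r_g >= -1, cfg$r_g <= 1, cfg$missing_rate >= 0,
            cfg$missing_rate < 1, cfg$n_founders >= 2, cfg$lines_per_set >= 1,
            cfg$replicates >= 1, cfg$years >= 1, cfg$locations >= 1,
            cfg$sigma_g2_f5 >= 0, cfg$sigma_g2_f6 >= 0, cfg$sigma_s2 >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder, check and SSD line genotypes with their pedigree
#'
#' Founders are unrelated inbred lines with marker allele frequencies drawn
#' uniformly on (0.05, 0.5). Each SSD line descends from a biparental cross
#' (families of \code{family_size} full sibs) advanced by per-marker
#' Mendelian gene dropping through \code{ssd_selfings} rounds of
#' self-fertilisation. Check lines are additional inbred founder-type
#' entries shared by all trials. A \code{missing_rate} fraction of the
#' emitted genotype calls is masked.
#'
#' @param cfg a [sim_config()].
#' @return list of class \code{"ssd_population"}: \code{genotypes} (masked
#'   [genotype_matrix()] over lines and checks), \code{genotypes_true}
#'   (complete counts), \code{pedigree}, \code{line_info} (line, set,
#'   family, is_check).
#' @export
simulate_population <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$n_markers
  p0 <- stats::runif(m, 0.05, 0.5)
  founder_ids <- sprintf("FND%02d", seq_len(cfg$n_founders))
  founders <- t(vapply(founder_ids,
                       function(id) 2 * (stats::runif(m) < p0), numeric(m)))
  check_ids <- if (cfg$n_checks > 0) sprintf("CHK%02d", seq_len(cfg$n_checks)) else character(0)
  checks <- if (length(check_ids) > 0)
    t(vapply(check_ids, function(id) 2 * (stats::runif(m) < p0), numeric(m)))
  else matrix(0, 0, m)

  n_fam <- ceiling(cfg$lines_per_set / cfg$family_size)
  recs <- list(); geno <- list(); info <- list()
  for (s in seq_len(cfg$n_sets)) {
    fam_par <- t(replicate(n_fam, sample(cfg$n_founders, 2)))
    made <- 0
    for (f in seq_len(n_fam)) {
      take <- min(cfg$family_size, cfg$lines_per_set - made)
      if (take <= 0) break
      h_a <- founders[fam_par[f, 1], ] / 2
      h_b <- founders[fam_par[f, 2], ] / 2
      for (l in seq_len(take)) {
        made <- made + 1
        id <- sprintf("S%d_L%03d", s, made)
        h1 <- h_a; h2 <- h_b
        for (r in seq_len(cfg$ssd_selfings)) {
          n1 <- ifelse(stats::runif(m) < 0.5, h1, h2)
          n2 <- ifelse(stats::runif(m) < 0.5, h1, h2)
          h1 <- n1; h2 <- n2
        }
        geno[[id]] <- h1 + h2
        recs[[id]] <- data.frame(id = id,
                                 parent1 = founder_ids[fam_par[f, 1]],
                                 parent2 = founder_ids[fam_par[f, 2]],
                                 selfing_cycles = cfg$ssd_selfings)
        info[[id]] <- data.frame(line = id, set = s,
                                 family = sprintf("S%d_F%02d", s, f),
                                 is_check = FALSE)
      }
    }
  }
  counts_true <- rbind(do.call(rbind, geno), checks)
  rownames(counts_true) <- c(names(geno), check_ids)
  colnames(counts_true) <- sprintf("M%04d", seq_len(m))
  counts <- counts_true
  if (cfg$missing_rate > 0)
    counts[matrix(stats::runif(length(counts)) < cfg$missing_rate,
                  nrow(counts))] <- NA
  ped <- pedigree(rbind(
    data.frame(id = founder_ids, parent1 = NA, parent2 = NA,
               selfing_cycles = cfg$founder_selfing),
    if (length(check_ids) > 0)
      data.frame(id = check_ids, parent1 = NA, parent2 = NA,
                 selfing_cycles = cfg$founder_selfing),
    do.call(rbind, recs)))
  line_info <- rbind(do.call(rbind, info),
                     if (length(check_ids) > 0)
                       data.frame(line = check_ids, set = NA,
                                  family = NA, is_check = TRUE))
  rownames(line_info) <- NULL
  rownames(founders) <- founder_ids
  colnames(founders) <- colnames(counts_true)
  structure(list(genotypes = genotype_matrix(counts),
                 genotypes_true = counts_true, founders = founders,
                 pedigree = ped, line_info = line_info, config = cfg),
            class = "ssd_population")
}

# sum of iid position effects over the <=9-plot Moore neighbourhood of a
# full nrow x ncol grid of effects u
ma9_surface <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  s <- matrix(0, nr, nc)
  for (dx in -1:1) for (dy in -1:1) {
    r0 <- max(1, 1 + dy); r1 <- min(nr, nr + dy)
    c0 <- max(1, 1 + dx); c1 <- min(nc, nc + dx)
    if (r0 > r1 || c0 > c1) next
    rs <- r0:r1; cs <- c0:c1
    s[rs - dy, cs - dx] <- s[rs - dy, cs - dx] + u[rs, cs]
  }
  s
}

#' Simulate multi-environment field trials with stored ground truth
#'
#' Bivariate marker effects with genetic correlation \code{r_g} generate
#' true breeding values for the F5 and F6 trait expressions (covariance
#' exactly \code{H x G} for the realised genotypes). Each set's F6 lines
#' are partitioned into trials carrying every check; each trial is laid out
#' as a replicates-by-entries grid with randomized complete blocks (one
#' replicate per row). Year-location-trial effects are drawn iid; F6 plot
#' errors include the 9-plot moving-average surface and F5 plots row+column
#' effects — exactly the forms the models fit.
#'
#' @param cfg a [sim_config()].
#' @param pop a [simulate_population()] result.
#' @return list with \code{plots} (a [plot_table()]) and \code{truth}
#'   (marker effects, true breeding values, the generating variance
#'   components, realised genetic correlation).
#' @export
simulate_trials <- function(cfg, pop) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1)
  M <- pop$genotypes_true
  p <- colMeans(M) / 2
  den <- 2 * sum(p * (1 - p))
  Z <- sweep(M, 2, 2 * p, "-")
  H <- matrix(c(cfg$sigma_g2_f5,
                cfg$r_g * sqrt(cfg$sigma_g2_f5 * cfg$sigma_g2_f6),
                cfg$r_g * sqrt(cfg$sigma_g2_f5 * cfg$sigma_g2_f6),
                cfg$sigma_g2_f6), 2)
  alpha <- matrix(stats::rnorm(2 * ncol(M)), ncol = 2) %*% t(psd_sqrt(H / den))
  bv <- Z %*% alpha
  colnames(bv) <- c("F5", "F6")

  info <- pop$line_info
  check_ids <- info$line[info$is_check]
  rows <- list(); pid <- 0
  add <- function(line, gen, set, year, loc, trial, rep, x, y, yld, chk) {
    pid <<- pid + 1
    data.frame(plot_id = sprintf("P%06d", pid), line = line, generation = gen,
               set = set, year = year, location = loc, trial = trial,
               replicate = rep, x = x, y = y, yield = max(yld, 1e-3),
               is_check = chk)
  }

  for (s in seq_len(cfg$n_sets)) {
    set_lines <- info$line[!info$is_check & info$set == s]
    # F5: one year, one location, one plot per line, near-square grid
    n <- length(set_lines)
    nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
    ord <- sample(set_lines)
    xs <- (seq_len(n) - 1) %% nc
    ys <- (seq_len(n) - 1) %/% nc
    rowe <- stats::rnorm(nr, 0, sqrt(cfg$sigma_s2))
    cole <- stats::rnorm(nc, 0, sqrt(cfg$sigma_s2))
    ylt5 <- stats::rnorm(1, 0, sqrt(cfg$sigma_ylt2))
    yld5 <- cfg$mean_f5 + ylt5 + bv[ord, "F5"] + rowe[ys + 1] + cole[xs + 1] +
      stats::rnorm(n, 0, sqrt(cfg$sigma_e2_f5))
    rows[[length(rows) + 1]] <- do.call(rbind, lapply(seq_len(n), function(i)
      add(ord[i], "F5", s, 2011 + s, "Loc1", sprintf("S%dF5", s), 1,
          xs[i], ys[i], yld5[i], FALSE)))

    # F6: trials of trial_lines + checks, replicate rows, years x locations
    chunks <- split(set_lines, ceiling(seq_along(set_lines) / cfg$trial_lines))
    for (tix in seq_along(chunks)) {
      entries <- c(chunks[[tix]], check_ids)
      ne <- length(entries)
      trial_id <- sprintf("S%dT%02d", s, tix)
      for (yr in seq_len(cfg$years)) {
        year <- 2012 + s + yr - 1
        for (lc in seq_len(cfg$locations)) {
          loc <- sprintf("Loc%d", lc)
          ylt <- stats::rnorm(1, 0, sqrt(cfg$sigma_ylt2))
          u <- matrix(stats::rnorm(cfg$replicates * ne, 0, sqrt(cfg$sigma_s2)),
                      cfg$replicates, ne)
          spat <- ma9_surface(u)
          for (rp in seq_len(cfg$replicates)) {
            ordE <- sample(entries)
            yld <- cfg$mean_f6 + ylt + bv[ordE, "F6"] + spat[rp, ] +
              stats::rnorm(ne, 0, sqrt(cfg$sigma_e2_f6))
            rows[[length(rows) + 1]] <- do.call(rbind, lapply(seq_len(ne),
              function(i) add(ordE[i], "F6", s, year, loc, trial_id, rp,
                              i - 1, rp - 1, yld[i], ordE[i] %in% check_ids)))
          }
        }
      }
    }
  }
  plots <- plot_table(do.call(rbind, rows))
  keep <- !info$is_check
  truth <- list(marker_effects = alpha,
                bv = data.frame(line = rownames(bv), bv_f5 = bv[, "F5"],
                                bv_f6 = bv[, "F6"], row.names = NULL),
                vc_true = list(sigma_g2_f5 = cfg$sigma_g2_f5,
                               sigma_g2_f6 = cfg$sigma_g2_f6,
                               sigma_e2_f5 = cfg$sigma_e2_f5,
                               sigma_e2_f6 = cfg$sigma_e2_f6,
                               sigma_s2 = cfg$sigma_s2,
                               sigma_ylt2 = cfg$sigma_ylt2, r_g = cfg$r_g),
                realized_r_g = stats::cor(bv[keep, "F5"], bv[keep, "F6"]),
                seed = cfg$seed)
  list(plots = plots, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_population()] and
#' [simulate_trials()].
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genotypes}, \code{genotypes_true},
#'   \code{pedigree}, \code{line_info}, \code{plots}, \code{truth},
#'   \code{config}.
#' @export
simulate_study <- function(cfg = sim_config()) {
  pop <- simulate_population(cfg)
  tr <- simulate_trials(cfg, pop)
  list(genotypes = pop$genotypes, genotypes_true = pop$genotypes_true,
       pedigree = pop$pedigree, line_info = pop$line_info,
       plots = tr$plots, truth = tr$truth, config = cfg)
}
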