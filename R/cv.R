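#' Forward cross-validation split
#'
#' Splits plot records forward in time: the newest set is the validation
#' population. Single-trait training uses F6 records of the remaining sets
#' only; multi-trait training additionally includes the F5 records of
#' \emph{all} sets — the validation lines' F5 plots are deliberately part of
#' the training data, which is what lets the bivariate model transfer
#' information to their unobserved F6 trait. Validation records are the F6
#' plots of the held-out set in both cases.
#'
#' @param plots plot table.
#' @param validation_set set label held out (default 4).
#' @param mode \code{"stgp"} (single-trait) or \code{"mtgp"} (multi-trait).
#' @return list with \code{train} and \code{validation} plot tables.
#' @export
forward_split <- function(plots, validation_set = 4, mode = c("stgp", "mtgp")) {
  mode <- match.arg(mode)
  plots <- as.data.frame(plots)
  if (!validation_set %in% plots$set)
    stop("validation set ", validation_set, " has no plots")
  val <- plots[plots$generation == "F6" & plots$set == validation_set, ,
               drop = FALSE]
  if (nrow(val) == 0) stop("validation set ", validation_set, " has no F6 plots")
  train <- if (mode == "stgp") {
    plots[plots$generation == "F6" & plots$set != validation_set, , drop = FALSE]
  } else {
    plots[(plots$generation == "F6" & plots$set != validation_set) |
            plots$generation == "F5", , drop = FALSE]
  }
  if (nrow(train) == 0) stop("empty training split")
  list(train = train, validation = val)
}

#' Fixed-effect-corrected line means
#'
#' Averages, per line, the validation yields corrected for their
#' year-location-trial effects: \code{mean(y - x'b)}. With
#' \code{method = "blup"} (default) the YLT effects are estimated from the
#' validation records alone with the line effect treated as random under
#' \code{G}, so no training phenotypes enter the correction;
#' \code{method = "centering"} subtracts plain within-YLT means.
#'
#' @param plots validation plot table (one generation).
#' @param G genomic relationship matrix (used by the \code{"blup"} method).
#' @param method correction method.
#' @param exclude_checks drop check entries from the returned means.
#' @return named vector of corrected line means.
#' @export
corrected_line_means <- function(plots, G = NULL,
                                 method = c("blup", "centering"),
                                 exclude_checks = TRUE) {
  method <- match.arg(method)
  plots <- as.data.frame(plots)
  plots <- plots[!is.na(plots$yield), , drop = FALSE]
  gen <- unique(plots$generation)
  if (length(gen) != 1) stop("corrected means expect a single generation")
  ylt <- paste(plots$year, plots$location, plots$trial, sep = ":")
  one_line <- tapply(plots$line, ylt, function(l) length(unique(l)) == 1)
  if (any(one_line))
    warning("YLT level(s) with a single line: correction confounded with the line effect")
  if (method == "blup") {
    if (is.null(G)) stop("method 'blup' needs G")
    fit <- gblup(plots, G, generation = gen)
    b <- coef(fit)
    corr <- plots$yield - unname(b[ylt])
  } else {
    corr <- plots$yield - stats::ave(plots$yield, ylt)
  }
  if (exclude_checks) {
    corr <- corr[!plots$is_check]
    line <- plots$line[!plots$is_check]
  } else line <- plots$line
  means <- tapply(corr, line, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Predictive ability
#'
#' Pearson correlation between fixed-effect-corrected line-mean yields and
#' estimated breeding values over the validation lines common to both.
#'
#' @param y_bar_c named vector of corrected line means.
#' @param g_hat named vector of EBVs.
#' @return scalar correlation.
#' @export
predictive_ability <- function(y_bar_c, g_hat) {
  common <- intersect(names(y_bar_c), names(g_hat))
  if (length(common) < 3) stop("need at least 3 lines with both values")
  a <- y_bar_c[common]; b <- g_hat[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in corrected means or EBVs")
  stats::cor(a, b)
}

#' Prediction accuracy
#'
#' Predictive ability divided by the square root of the heritability of
#' line means.
#'
#' @param rho predictive ability.
#' @param h2_line heritability of line means, in (0, 1].
#' @return scalar accuracy.
#' @export
prediction_accuracy <- function(rho, h2_line) {
  if (!is.finite(h2_line) || h2_line <= 0 || h2_line > 1)
    stop("h2_line must be in (0, 1]")
  rho / sqrt(h2_line)
}

#' Compare single- and multi-trait genomic prediction configurations
#'
#' Runs the forward cross-validation for the four standard configurations —
#' STGP and MTGP, each with the genomic matrix alone and with
#' genomic + pedigree + spatial terms — on a shared split, and reports
#' predictive ability and accuracy per configuration.
#'
#' @param plots plot table with F5 and F6 records and set labels.
#' @param G genomic relationship matrix (conditioned PD).
#' @param A pedigree relationship matrix (needed for the \code{"G+A+spatial"}
#'   rows; skipped with a message when absent).
#' @param validation_set held-out set (default 4).
#' @param include_checks_in_rho include check entries among the validation
#'   lines (default FALSE).
#' @param correction method for [corrected_line_means()].
#' @param ... passed to [gblup()] (e.g. \code{tol}, \code{max_iter}).
#' @return data.frame of class \code{"cv_report"}: model, relmat, n_lines,
#'   rho, accuracy, h2_line.
#' @export
compare_models <- function(plots, G, A = NULL, validation_set = 4,
                           include_checks_in_rho = FALSE,
                           correction = "blup", ...) {
  plots <- as.data.frame(plots)
  configs <- expand.grid(model = c("STGP", "MTGP"),
                         relmat = c("G", "G+A+spatial"),
                         stringsAsFactors = FALSE)
  if (is.null(A)) {
    message("no pedigree matrix supplied; reporting G-only configurations")
    configs <- configs[configs$relmat == "G", , drop = FALSE]
  }
  split_s <- forward_split(plots, validation_set, "stgp")
  split_m <- forward_split(plots, validation_set, "mtgp")
  ybar <- corrected_line_means(split_s$validation, G, method = correction,
                               exclude_checks = !include_checks_in_rho)
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    mtgp <- configs$model[i] == "MTGP"
    full <- configs$relmat[i] == "G+A+spatial"
    sp <- if (mtgp) split_m else split_s
    fit <- gblup(sp$train, G, A = if (full) A,
                 generation = if (mtgp) c("F5", "F6") else "F6",
                 spatial = full, ...)
    g_hat <- predict(fit, trait = "F6")
    rho <- predictive_ability(ybar, g_hat)
    h <- heritability(fit)
    h2l <- h$h2_line[h$trait == "F6"]
    data.frame(model = configs$model[i], relmat = configs$relmat[i],
               n_lines = length(intersect(names(ybar), names(g_hat))),
               rho = rho,
               accuracy = prediction_accuracy(rho, min(h2l, 1)),
               h2_line = h2l)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_report", "data.frame")
  out
}

#' @export
plot.cv_report <- function(x, ...) {
  lab <- paste(x$model, x$relmat)
  graphics::barplot(x$rho, names.arg = lab, las = 2,
                    ylab = expression(rho(bar(y)[c], hat(g))),
                    main = "Forward-validation predictive ability", ...)
  invisible(x)
}
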