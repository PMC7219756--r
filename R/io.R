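#' Read a line-by-marker genotype table
#'
#' Reads a delimited text file of minor-allele counts (0, 1, 2) with one row
#' per breeding line and one column per marker. The first column holds line
#' identifiers and the header row holds marker identifiers. Missing calls are
#' encoded by \code{na} (default \code{"NA"}).
#'
#' @param path path to a delimited text file.
#' @param dialect \code{"tsv"} (canonical) or \code{"csv"}.
#' @param na token representing a missing genotype call.
#' @return A numeric matrix of class \code{"genotype_matrix"} with line ids as
#'   row names and marker ids as column names; missing calls are \code{NA}.
#' @seealso [write_genotypes()], [qc_filter()], [build_G()]
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           na.strings = na, colClasses = "character",
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(!is.na(m) & (is.na(num) | !(num %in% c(0, 1, 2))),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid genotype value %s at line '%s', marker '%s' (must be 0/1/2/%s)",
      dQuote(m[bad[1, 1], bad[1, 2]]), rownames(m)[bad[1, 1]],
      colnames(m)[bad[1, 2]], na))
  }
  genotype_matrix(num)
}

#' Construct and validate a genotype matrix
#'
#' @param counts numeric matrix of minor-allele counts in \{0,1,2,NA\} with
#'   line ids as row names, marker ids as column names.
#' @return the validated matrix, classed \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("genotype matrix needs line ids (row names) and marker ids (col names)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate line ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (nrow(counts) < 2) stop("need at least 2 lines")
  if (ncol(counts) < 1) stop("need at least 1 marker")
  v <- counts[!is.na(counts)]
  if (any(!(v %in% c(0, 1, 2))))
    stop("genotype calls must be 0, 1, 2 or missing")
  class(counts) <- c("genotype_matrix", class(counts))
  counts
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] for the canonical dialect; a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param g genotype matrix.
#' @param path output path.
#' @inheritParams read_genotypes
#' @export
write_genotypes <- function(g, path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(line = rownames(g), unclass(g), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

#' Read a pedigree table
#'
#' Expects columns \code{id}, \code{parent1}, \code{parent2} and
#' \code{selfing_cycles} (rounds of self-fertilisation applied after the
#' cross; for founders, the number assumed for the parental line itself).
#' Unknown parents are the \code{na} token or empty. Rows may be in any
#' order; a topological order is computed and cycles are rejected.
#'
#' @inheritParams read_genotypes
#' @return data.frame of class \code{"pedigree"} in topological order with
#'   columns id, parent1, parent2, selfing_cycles, founder.
#' @export
read_pedigree <- function(path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c(na, ""),
                          colClasses = "character", check.names = FALSE)
  need <- c("id", "parent1", "parent2", "selfing_cycles")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("pedigree file lacks columns: ", paste(miss, collapse = ", "))
  pedigree(data.frame(id = df$id, parent1 = df$parent1, parent2 = df$parent2,
                      selfing_cycles = as.integer(df$selfing_cycles),
                      stringsAsFactors = FALSE))
}

#' Construct and validate a pedigree
#'
#' @param df data.frame with columns id, parent1, parent2, selfing_cycles
#'   (parents \code{NA} when unknown).
#' @return pedigree in topological order (parents before offspring), with a
#'   derived \code{founder} flag (both parents unknown).
#' @export
pedigree <- function(df) {
  if (anyDuplicated(df$id))
    stop("duplicate pedigree ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (p in c(df$parent1, df$parent2)) {
    if (!is.na(p) && !(p %in% df$id))
      stop("parent '", p, "' has no pedigree record")
  }
  if (any(is.na(df$selfing_cycles) | df$selfing_cycles < 0))
    stop("selfing_cycles must be non-negative integers")
  ord <- ped_toposort(df)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$founder <- is.na(out$parent1) & is.na(out$parent2)
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn's algorithm; on failure reports the ids stuck in a cycle.
ped_toposort <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(df$parent1[i], df$parent2[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        if (j == i) stop("pedigree cycle: '", df$id[i], "' is its own parent")
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (j in children[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(df$id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Write a pedigree table
#' @param ped pedigree.
#' @param path output path.
#' @inheritParams read_genotypes
#' @export
write_pedigree <- function(ped, path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(ped[, c("id", "parent1", "parent2", "selfing_cycles")],
                     path, sep = sep, quote = FALSE, row.names = FALSE, na = na)
  invisible(path)
}

PLOT_COLUMNS <- c("plot_id", "line", "generation", "set", "year", "location",
                  "trial", "replicate", "x", "y", "yield", "is_check")

#' Read a field-plot table
#'
#' One row per field plot with columns \code{plot_id, line, generation (F5 or
#' F6), set, year, location, trial, replicate, x, y, yield, is_check}.
#' Coordinates \code{x} (column) and \code{y} (row) are 0-based integers on a
#' per-(year, location, trial) grid; yield is kg grain per plot.
#'
#' @inheritParams read_genotypes
#' @return data.frame of class \code{"plot_table"}.
#' @export
read_plots <- function(path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("plot file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(PLOT_COLUMNS, names(df))
  if (length(miss) > 0) stop("plot file lacks columns: ", paste(miss, collapse = ", "))
  df$is_check <- as.logical(df$is_check)
  plot_table(df)
}

#' Construct and validate a plot table
#'
#' @param df data.frame with the columns listed under [read_plots()].
#' @return validated data.frame of class \code{"plot_table"}.
#' @export
plot_table <- function(df) {
  miss <- setdiff(PLOT_COLUMNS, names(df))
  if (length(miss) > 0) stop("plot table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$generation %in% c("F5", "F6")))
    stop("generation must be 'F5' or 'F6'")
  key <- paste(df$year, df$location, df$trial, df$x, df$y, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("duplicate plot coordinates within (year, location, trial): ",
         paste(utils::head(unique(paste0("(", d$year, ",", d$location, ",",
                                         d$trial, ",", d$x, ",", d$y, ")")), 3),
               collapse = " "))
  }
  if (any(!is.na(df$yield) & df$yield <= 0)) stop("yield must be positive")
  f5 <- df[df$generation == "F5" & !df$is_check, ]
  if (nrow(f5) > 0 && anyDuplicated(f5$line))
    stop("F5 lines must have exactly one plot each; duplicated: ",
         paste(utils::head(unique(f5$line[duplicated(f5$line)]), 5), collapse = ", "))
  class(df) <- unique(c("plot_table", class(df)))
  df
}

#' Write a plot table
#' @param plots plot table.
#' @param path output path.
#' @inheritParams read_genotypes
#' @export
write_plots <- function(plots, path, dialect = c("tsv", "csv"), na = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(plots)[, PLOT_COLUMNS], path, sep = sep,
                     quote = FALSE, row.names = FALSE, na = na)
  invisible(path)
}

#' Descriptive statistics of yield records per generation
#'
#' Number of plots, mean, standard deviation (n-1 denominator), minimum and
#' maximum of yield, one row per generation present in the table. A
#' single-plot group reports SD 0 with a warning.
#'
#' @param plots plot table.
#' @return data.frame with columns generation, n_plots, mean, sd, min, max.
#' @export
summarize_phenotypes <- function(plots) {
  plots <- plots[!is.na(plots$yield), , drop = FALSE]
  if (nrow(plots) == 0) stop("no yield records")
  gens <- sort(unique(plots$generation))
  rows <- lapply(gens, function(g) {
    y <- plots$yield[plots$generation == g]
    s <- if (length(y) == 1) {
      warning("single plot in generation ", g, "; SD reported as 0")
      0
    } else stats::sd(y)
    data.frame(generation = g, n_plots = length(y), mean = mean(y), sd = s,
               min = min(y), max = max(y))
  })
  do.call(rbind, rows)
}
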