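#' Construct a single-cell genotype matrix
#'
#' An `scs_matrix` is an n x m ternary matrix of single-cell mutation calls:
#' rows are cells, columns are mutations, entries are `0` (mutation absent),
#' `1` (mutation present) or `NA` (missing, i.e. insufficient coverage to
#' call the site).
#'
#' @param x integer or numeric matrix with entries in \{0, 1, NA\}.
#' @param cell_labels character vector of row names (default `"cell1"`, ...).
#' @param mutation_labels character vector of column names (default
#'   `"mut1"`, ...).
#' @return an `scs_matrix`: an integer matrix with dimnames and class
#'   attribute.
#' @examples
#' I <- scs_matrix(rbind(c(0, 1, NA), c(1, 0, NA)))
#' I
#' @export
scs_matrix <- function(x, cell_labels = NULL, mutation_labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("genotype matrix must have at least one cell and one mutation")
  storage.mode(x) <- "integer"
  bad <- which(!(x %in% c(0L, 1L, NA_integer_)))
  if (length(bad))
    stop("invalid genotype entries (must be 0, 1 or NA) at position(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (is.null(cell_labels)) {
    cell_labels <- rownames(x)
    if (is.null(cell_labels)) cell_labels <- paste0("cell", seq_len(nrow(x)))
  }
  if (is.null(mutation_labels)) {
    mutation_labels <- colnames(x)
    if (is.null(mutation_labels)) mutation_labels <- paste0("mut", seq_len(ncol(x)))
  }
  if (length(cell_labels) != nrow(x))
    stop("cell_labels length (", length(cell_labels), ") != number of rows (",
         nrow(x), ")")
  if (length(mutation_labels) != ncol(x))
    stop("mutation_labels length (", length(mutation_labels),
         ") != number of columns (", ncol(x), ")")
  dimnames(x) <- list(cell_labels, mutation_labels)
  class(x) <- c("scs_matrix", "matrix")
  x
}

#' @export
print.scs_matrix <- function(x, ...) {
  cat("Single-cell genotype matrix: ", nrow(x), " cells x ", ncol(x),
      " mutations (", sum(is.na(x)), " missing entries)\n", sep = "")
  y <- unclass(x)
  if (nrow(y) > 10L || ncol(y) > 12L) {
    cat("First entries:\n")
    print(y[seq_len(min(10L, nrow(y))), seq_len(min(12L, ncol(y))), drop = FALSE])
  } else {
    print(y)
  }
  invisible(x)
}

#' Read a single-cell genotype matrix from a text file
#'
#' Reads a whitespace-separated ternary matrix.  Tokens `0` and `1` are
#' genotype calls; both `2` and `?` denote a missing entry.  The file may be
#' laid out with cells as rows (default) or mutations as rows (many
#' mutation-tree tools use the transposed layout); the latter is transposed
#' on load so that the returned matrix always has cells as rows.
#'
#' @param path path to the matrix file.
#' @param dialect `"cells-as-rows"` (default) or `"mutations-as-rows"`.
#' @param cell_labels,mutation_labels optional paths to one-name-per-line
#'   label files, or character vectors of labels.
#' @return an [scs_matrix()].
#' @seealso [write_scs_matrix()], [read_rate_file()]
#' @export
read_scs_matrix <- function(path,
                            dialect = c("cells-as-rows", "mutations-as-rows"),
                            cell_labels = NULL, mutation_labels = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  width <- lengths(toks)
  if (any(width != width[1L]))
    stop("ragged matrix file ", path, ": row ", which(width != width[1L])[1L],
         " has ", width[which(width != width[1L])[1L]], " tokens, expected ",
         width[1L])
  tok <- unlist(toks, use.names = FALSE)
  ok <- tok %in% c("0", "1", "2", "?")
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop("invalid token '", tok[i], "' in ", path, " (row ",
         ceiling(i / width[1L]), ", column ", (i - 1L) %% width[1L] + 1L,
         "): expected one of 0, 1, 2, ?")
  }
  val <- rep(NA_integer_, length(tok))
  val[tok == "0"] <- 0L
  val[tok == "1"] <- 1L
  x <- matrix(val, nrow = length(lines), ncol = width[1L], byrow = TRUE)
  if (dialect == "mutations-as-rows") x <- t(x)
  read_labels <- function(l, n, what) {
    if (is.null(l)) return(NULL)
    if (length(l) == 1L && file.exists(l)) l <- readLines(l)
    l <- l[nzchar(trimws(l))]
    if (length(l) != n)
      stop(what, " label file has ", length(l), " names, expected ", n)
    trimws(l)
  }
  scs_matrix(x,
             cell_labels = read_labels(cell_labels, nrow(x), "cell"),
             mutation_labels = read_labels(mutation_labels, ncol(x), "mutation"))
}

#' Write a single-cell genotype matrix to a text file
#'
#' Missing entries are written as `?`.  Inverse of [read_scs_matrix()] with
#' the same dialect.
#'
#' @inheritParams read_scs_matrix
#' @param x an [scs_matrix()] or a plain 0/1/NA matrix.
#' @return `path`, invisibly.
#' @export
write_scs_matrix <- function(x, path,
                             dialect = c("cells-as-rows", "mutations-as-rows")) {
  dialect <- match.arg(dialect)
  y <- unclass(x)
  if (dialect == "mutations-as-rows") y <- t(y)
  ch <- matrix(as.character(y), nrow(y), ncol(y))
  ch[is.na(ch)] <- "?"
  writeLines(apply(ch, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Read a per-mutation rate file
#'
#' A rate file holds either a single value, broadcast to all m mutations
#' (a homogeneous rate), or exactly m values, one per line.
#'
#' @param path path to the rate file.
#' @param m number of mutations.
#' @return numeric vector of length `m`, each value in \eqn{[0, 1)}.
#' @export
read_rate_file <- function(path, m) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 1L) vals <- rep(vals, m)
  if (length(vals) != m)
    stop("rate file ", path, " has ", length(vals),
         " values; expected 1 or ", m)
  if (any(vals < 0 | vals >= 1))
    stop("rates must lie in [0, 1); offending value: ",
         vals[which(vals < 0 | vals >= 1)[1L]])
  vals
}

#' Bundle the error-model rates
#'
#' The error model has a false-negative (allelic dropout) rate `alpha[j]`
#' per mutation, a single global false-positive rate `beta`, and a prior
#' loss probability `gamma[j]` per mutation (`gamma[j] = 0` declares a
#' mutation unlosable).
#'
#' @param alpha per-mutation false-negative rates; a scalar is broadcast.
#' @param beta global false-positive rate.
#' @param gamma per-mutation prior loss probabilities; a scalar is broadcast.
#' @param m number of mutations.
#' @return an object of class `error_rates`: a list with elements `alpha`,
#'   `beta`, `gamma`, `m`.
#' @examples
#' error_rates(alpha = 0.1, beta = 1e-5, gamma = 0.05, m = 4)
#' @export
error_rates <- function(alpha, beta, gamma, m) {
  if (length(alpha) == 1L) alpha <- rep(as.numeric(alpha), m)
  if (length(gamma) == 1L) gamma <- rep(as.numeric(gamma), m)
  if (length(alpha) != m) stop("alpha must have length 1 or m = ", m)
  if (length(gamma) != m) stop("gamma must have length 1 or m = ", m)
  if (length(beta) != 1L) stop("beta must be a single rate")
  chk <- function(x, nm) {
    if (any(x < 0 | x >= 1))
      stop(nm, " rates must lie in [0, 1)")
  }
  chk(alpha, "alpha"); chk(beta, "beta"); chk(gamma, "gamma")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), m = as.integer(m)),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat("Error rates for", x$m, "mutations\n")
  cat("  false-negative alpha: ",
      if (length(unique(x$alpha)) == 1L) format(x$alpha[1L])
      else paste0("per-mutation, mean ", format(signif(mean(x$alpha), 3))), "\n",
      sep = "")
  cat("  false-positive beta:  ", format(x$beta), "\n", sep = "")
  cat("  loss prior gamma:     ",
      if (length(unique(x$gamma)) == 1L) format(x$gamma[1L])
      else paste0("per-mutation, mean ", format(signif(mean(x$gamma), 3))), "\n",
      sep = "")
  invisible(x)
}
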