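# Relationship matrices: the pedigree-based numerator relationship matrix A
# (tabular method) and the marker-based genomic relationship matrix G
# (VanRaden's first method).

#' Construct a relationship-matrix object
#'
#' @param m symmetric numeric matrix with individual ids as dimnames.
#' @param kind "A" (pedigree) or "G" (genomic).
#' @param ridge ridge constant to add to the diagonal before
#'   inversion-bearing uses (recorded, not applied to the stored matrix).
#' @param freq_source for G, how allele frequencies were obtained.
#' @return object of class \code{relmat} (a matrix with metadata).
#' @export
relmat <- function(m, kind = c("A", "G"), ridge = 0, freq_source = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
    stop("relationship matrix is not symmetric")
  structure(m, class = c("relmat", "matrix"), kind = kind, ridge = ridge,
            freq_source = freq_source)
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals (ridge %.1g)\n",
              attr(x, "kind"), nrow(x), attr(x, "ridge")))
  invisible(x)
}

# plain matrix view (drops the relmat class but keeps dimnames)
relmat_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL; attr(m, "ridge") <- NULL
  attr(m, "freq_source") <- NULL
  m
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Classical recursion over a topologically ordered pedigree:
#' \code{A[i,i] = 1 + 0.5 * A[sire, dam]} and for earlier j
#' \code{A[i,j] = 0.5 * (A[j, sire] + A[j, dam])}; an unknown parent
#' contributes zero. The diagonal is 1 plus the inbreeding coefficient.
#'
#' @param pedigree data.frame with columns id, sire, dam (NA or "0" for
#'   unknown), in topological order (parents before offspring).
#' @return a \code{relmat} of kind "A".
#' @export
pedigree_a_matrix <- function(pedigree) {
  ped <- normalize_pedigree_parents(pedigree)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (anyNA(si) || anyNA(di))
    stop("parent id absent from pedigree")
  if (any(si >= seq_len(n) & si > 0L) || any(di >= seq_len(n) & di > 0L))
    stop("pedigree is not topologically ordered (or an individual is its own ancestor)")

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  relmat(A, kind = "A")
}

# Accept "0" or "" as unknown parent; returns pedigree with NA for unknown.
normalize_pedigree_parents <- function(pedigree) {
  stopifnot(is.data.frame(pedigree), all(c("id", "sire", "dam") %in% names(pedigree)))
  ped <- pedigree
  ped$id <- as.character(ped$id)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  fix <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  ped$sire <- fix(ped$sire)
  ped$dam <- fix(ped$dam)
  ped
}

#' Genomic relationship matrix (VanRaden, first method)
#'
#' \code{Z} is the dosage matrix with column j centred by \code{2 p_j};
#' \code{G = Z Z' / (2 sum_j p_j (1 - p_j))}. By default frequencies are
#' computed from the supplied (imputed) genotypes themselves; an external
#' frequency vector (e.g. founder frequencies) may be given instead.
#' Monomorphic SNPs contribute zero to both numerator and denominator; a
#' wholly monomorphic panel is an error.
#'
#' @param geno a \code{genotypes} object with no missing entries.
#' @param allele_freqs optional per-SNP reference-allele frequencies in [0,1].
#' @param ridge ridge recorded in metadata and applied by inversion-bearing
#'   consumers (default 1e-6).
#' @return a \code{relmat} of kind "G".
#' @export
genomic_g_matrix <- function(geno, allele_freqs = NULL, ridge = 1e-6) {
  stopifnot(inherits(geno, "genotypes"))
  d <- geno$dosage
  if (anyNA(d)) stop("genotypes contain missing dosages; impute first")
  if (is.null(allele_freqs)) {
    p <- colMeans(d) / 2
    src <- "observed sample"
  } else {
    p <- allele_freqs
    src <- "external"
    if (length(p) != ncol(d)) stop("allele_freqs length mismatch")
  }
  if (any(p < 0 | p > 1)) stop("allele frequencies outside [0, 1]")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("wholly monomorphic SNP panel: G undefined")
  Z <- sweep(d, 2L, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  relmat(G, kind = "G", ridge = ridge, freq_source = src)
}

#' Write / read a relationship matrix as dense TSV
#'
#' Header row of individual ids; first column repeats the ids. The reader
#' validates symmetry.
#'
#' @param x a \code{relmat}.
#' @param path file path.
#' @return \code{read_relmat} returns a \code{relmat}.
#' @export
write_relmat <- function(x, path) {
  m <- relmat_matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @param kind kind flag to attach on read ("A" or "G").
#' @export
read_relmat <- function(path, kind = c("A", "G")) {
  kind <- match.arg(kind)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("matrix read from file is not symmetric")
  m <- (m + t(m)) / 2
  relmat(m, kind = kind)
}
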