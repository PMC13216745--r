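# Contact-list ingestion, proximity filtering, binning, iterative-correction
# balancing, distance-decay estimation and observed/expected matrices.

#' Construct a ContactSet
#'
#' Fragment-level ligation pairs. Cis records are canonicalized so
#' \code{pos1 <= pos2}; trans records are kept separately and excluded from
#' all cis-only analyses.
#'
#' @param cis data.frame with columns \code{chrom}, \code{pos1}, \code{pos2}.
#' @param chromsizes \code{ChromSizes} giving the coordinate context.
#' @param trans Optional data.frame with \code{chrom1,pos1,chrom2,pos2}.
#' @param replicate Replicate label.
#' @return An object of class \code{"ContactSet"}.
#' @export
contact_set <- function(cis, chromsizes, trans = NULL, replicate = "rep1") {
  if (is.null(trans))
    trans <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                        chrom2 = character(0), pos2 = numeric(0))
  cis <- as.data.frame(cis)
  unknown <- setdiff(unique(c(cis$chrom, trans$chrom1, trans$chrom2)),
                     names(chromsizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  swap <- cis$pos2 < cis$pos1
  if (any(swap)) {
    tmp <- cis$pos1[swap]
    cis$pos1[swap] <- cis$pos2[swap]
    cis$pos2[swap] <- tmp
  }
  if (nrow(cis)) {
    if (any(cis$pos1 < 1) || any(cis$pos2 > chromsizes[cis$chrom]))
      stop("contact position outside chromosome bounds")
  }
  structure(list(cis = cis, trans = trans, chromsizes = chromsizes,
                 replicate = replicate),
            class = "ContactSet")
}

#' @export
print.ContactSet <- function(x, ...) {
  cat("ContactSet (", x$replicate, "): ", nrow(x$cis), " cis, ",
      nrow(x$trans), " trans contacts on ", length(x$chromsizes),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a 4DN-style pairs file
#'
#' Lines starting with \code{#} are treated as header; a
#' \verb{#columns:} line, when present, locates the \code{chr1 pos1 chr2
#' pos2} fields, otherwise the standard layout (readID chr1 pos1 chr2 pos2
#' ...) or a bare 4-column layout is assumed.
#'
#' @param path Pairs file path.
#' @param chromsizes \code{ChromSizes}; positions outside it are an error.
#' @param replicate Replicate label to attach.
#' @return A \code{\link{contact_set}}.
#' @export
read_pairs <- function(path, chromsizes, replicate = "rep1") {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  cols_line <- hdr[startsWith(hdr, "#columns:")]
  if (length(body) == 0L)
    return(contact_set(data.frame(chrom = character(0), pos1 = numeric(0),
                                  pos2 = numeric(0)),
                       chromsizes, replicate = replicate))
  df <- read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  if (length(cols_line)) {
    cn <- strsplit(sub("^#columns:\\s*", "", cols_line[1]), "[ \t]+")[[1]]
    idx <- match(c("chr1", "pos1", "chr2", "pos2"), cn)
    if (anyNA(idx)) stop("pairs #columns header lacks chr1/pos1/chr2/pos2")
  } else if (ncol(df) >= 5) {
    idx <- 2:5
  } else if (ncol(df) == 4) {
    idx <- 1:4
  } else stop("pairs file needs at least 4 columns")
  chrom1 <- as.character(df[[idx[1]]]); pos1 <- as.numeric(df[[idx[2]]])
  chrom2 <- as.character(df[[idx[3]]]); pos2 <- as.numeric(df[[idx[4]]])
  is_cis <- chrom1 == chrom2
  contact_set(data.frame(chrom = chrom1[is_cis], pos1 = pos1[is_cis],
                         pos2 = pos2[is_cis], stringsAsFactors = FALSE),
              chromsizes,
              trans = data.frame(chrom1 = chrom1[!is_cis], pos1 = pos1[!is_cis],
                                 chrom2 = chrom2[!is_cis], pos2 = pos2[!is_cis],
                                 stringsAsFactors = FALSE),
              replicate = replicate)
}

#' Write a ContactSet as 4DN-style pairs text
#'
#' @param cs \code{ContactSet}.
#' @param path Output path.
#' @export
write_pairs <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               "#columns: readID chr1 pos1 chr2 pos2"), con)
  n_cis <- nrow(cs$cis)
  if (n_cis) {
    df <- data.frame(id = paste0("c", seq_len(n_cis)), c1 = cs$cis$chrom,
                     p1 = format(cs$cis$pos1, scientific = FALSE, trim = TRUE),
                     c2 = cs$cis$chrom,
                     p2 = format(cs$cis$pos2, scientific = FALSE, trim = TRUE))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (nrow(cs$trans)) {
    df <- data.frame(id = paste0("t", seq_len(nrow(cs$trans))),
                     c1 = cs$trans$chrom1,
                     p1 = format(cs$trans$pos1, scientific = FALSE, trim = TRUE),
                     c2 = cs$trans$chrom2,
                     p2 = format(cs$trans$pos2, scientific = FALSE, trim = TRUE))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Remove short-range cis contacts
#'
#' Micro-C proximity filter: cis contacts with separation strictly below
#' \code{min_sep} are removed (a pair at exactly \code{min_sep} is kept).
#' Trans records are untouched.
#'
#' @param cs \code{ContactSet}.
#' @param min_sep Minimum separation in bp (default 200).
#' @return Filtered \code{ContactSet}; the number removed is attached as the
#'   \code{n_removed} attribute.
#' @export
filter_min_distance <- function(cs, min_sep = 200) {
  keep <- (cs$cis$pos2 - cs$cis$pos1) >= min_sep
  out <- cs
  out$cis <- cs$cis[keep, , drop = FALSE]
  rownames(out$cis) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Bin a ContactSet into an upper-triangular sparse matrix
#'
#' Bin index of a 1-based position is \code{floor((pos - 1)/resolution)}
#' (0-based); the matrix sum equals the number of cis records.
#'
#' @param cs \code{ContactSet}.
#' @param resolution Bin size in bp.
#' @return An object of class \code{"BinnedMatrix"}: per-chromosome sparse
#'   upper-triangular count matrices plus (after \code{\link{ice_balance}})
#'   balancing weights and masked-bin flags.
#' @export
bin_contacts <- function(cs, resolution) {
  stopifnot(resolution > 0)
  chroms <- names(cs$chromsizes)
  mats <- lapply(chroms, function(ch) {
    n_bins <- as.integer(ceiling(cs$chromsizes[[ch]] / resolution))
    sel <- cs$cis$chrom == ch
    b1 <- floor((cs$cis$pos1[sel] - 1) / resolution) + 1
    b2 <- floor((cs$cis$pos2[sel] - 1) / resolution) + 1
    Matrix::sparseMatrix(i = b1, j = b2, x = rep(1, length(b1)),
                         dims = c(n_bins, n_bins))
  })
  names(mats) <- chroms
  structure(list(resolution = resolution, matrices = mats,
                 chromsizes = cs$chromsizes, weights = NULL, masked = NULL),
            class = "BinnedMatrix")
}

#' @export
print.BinnedMatrix <- function(x, ...) {
  cat("BinnedMatrix at ", x$resolution, " bp: ",
      paste(names(x$matrices), collapse = ", "),
      if (!is.null(x$weights)) " [balanced]" else " [raw]", "\n", sep = "")
  invisible(x)
}

# symmetric view of an upper-triangular count matrix (diagonal once)
.sym_counts <- function(m) {
  m + Matrix::t(m) - Matrix::Diagonal(x = Matrix::diag(m))
}

#' Iterative-correction (ICE) balancing
#'
#' Computes per-bin weights \eqn{b_i} such that the balanced matrix
#' \eqn{m_{ij}/(b_i b_j)} has equal marginals over unmasked bins. Bins with
#' zero marginal are masked and excluded from the convergence test. Only the
#' iterative-correction step is performed; no eigenvector decomposition is
#' involved anywhere downstream.
#'
#' @param m \code{BinnedMatrix}.
#' @param tol Maximum allowed relative deviation of unmasked marginals from
#'   their mean.
#' @param max_iter Iteration budget; non-convergence is an error carrying
#'   the last deviation.
#' @return \code{m} with \code{weights} (per-chromosome numeric vectors) and
#'   \code{masked} (logical vectors) filled in; per-chromosome iteration
#'   counts in attribute \code{iterations}.
#' @export
ice_balance <- function(m, tol = 1e-5, max_iter = 200) {
  res <- lapply(names(m$matrices), function(ch) {
    S <- .sym_counts(m$matrices[[ch]])
    n <- nrow(S)
    marg <- Matrix::rowSums(S)
    masked <- marg == 0
    b <- rep(1, n)
    if (all(masked))
      return(list(weights = b, masked = masked, iterations = 0L))
    dev <- Inf
    for (it in seq_len(max_iter)) {
      Sb <- Matrix::Diagonal(x = 1 / b) %*% S %*% Matrix::Diagonal(x = 1 / b)
      s <- Matrix::rowSums(Sb)
      mu <- mean(s[!masked])
      dev <- max(abs(s[!masked] / mu - 1))
      if (dev < tol) return(list(weights = b, masked = masked, iterations = it))
      b[!masked] <- b[!masked] * (s[!masked] / mu)
    }
    stop("ICE did not converge on ", ch, " within ", max_iter,
         " iterations (last deviation ", signif(dev, 3), ")")
  })
  names(res) <- names(m$matrices)
  m$weights <- lapply(res, `[[`, "weights")
  m$masked <- lapply(res, `[[`, "masked")
  attr(m, "iterations") <- vapply(res, `[[`, 0L, "iterations")
  m
}

# Log-spaced decay bin edges from min_sep up to and beyond the longest
# chromosome; bins_per_octave controls the grid fineness (1 = doubling).
decay_bin_edges <- function(chromsizes, min_sep = 200, bins_per_octave = 1) {
  top <- max(chromsizes)
  k <- ceiling(bins_per_octave * log2(top / min_sep))
  min_sep * 2^((0:k) / bins_per_octave)
}

#' Estimate the distance-decay curve of a ContactSet
#'
#' Normalized histogram of cis separations over log-spaced (doubling) bin
#' edges. Per-chromosome curves are retained alongside the pooled
#' (contact-weighted) curve.
#'
#' @param cs \code{ContactSet} with at least one cis record.
#' @param bin_edges Optional ascending edges in bp; default doubles from
#'   200 bp to the chromosome length. Separations below the first edge are
#'   counted into the first bin.
#' @return Object of class \code{"DecayCurve"}: \code{edges}, pooled
#'   \code{mass} (sums to 1), per-chromosome masses and counts.
#' @export
estimate_decay <- function(cs, bin_edges = NULL) {
  if (nrow(cs$cis) == 0L) stop("no cis contacts")
  if (is.null(bin_edges)) bin_edges <- decay_bin_edges(cs$chromsizes)
  nb <- length(bin_edges) - 1L
  assign_bin <- function(d) pmin(pmax(findInterval(d, bin_edges, rightmost.closed = TRUE), 1L), nb)
  per_chrom <- lapply(split(cs$cis$pos2 - cs$cis$pos1, cs$cis$chrom), function(d) {
    tabulate(assign_bin(d), nbins = nb)
  })
  counts <- Reduce(`+`, per_chrom)
  structure(list(edges = bin_edges, mass = counts / sum(counts),
                 counts = counts,
                 per_chrom = lapply(per_chrom, function(x) x / sum(x)),
                 per_chrom_counts = per_chrom,
                 n_cis = nrow(cs$cis)),
            class = "DecayCurve")
}

#' @export
print.DecayCurve <- function(x, ...) {
  cat("DecayCurve:", length(x$mass), "log-spaced bins over",
      format(x$edges[1], scientific = FALSE), "-",
      format(x$edges[length(x$edges)], scientific = FALSE), "bp,",
      x$n_cis, "contacts\n")
  invisible(x)
}

# Total-variation distance between two decay curves on shared edges.
decay_tv_distance <- function(a, b) {
  stopifnot(length(a$mass) == length(b$mass))
  0.5 * sum(abs(a$mass - b$mass))
}

#' Observed-over-expected matrix
#'
#' Divides each diagonal of the (balanced when available) matrix by its mean
#' over unmasked bins at that separation, removing the distance-decay trend.
#'
#' @param m \code{BinnedMatrix}, balanced via \code{\link{ice_balance}} or
#'   raw.
#' @return List per chromosome with the sparse O/E matrix (\code{oe}), the
#'   per-diagonal means (\code{diag_mean}) and masked flags. All-zero
#'   chromosomes are fully masked.
#' @export
observed_over_expected <- function(m) {
  out <- lapply(names(m$matrices), function(ch) {
    M <- m$matrices[[ch]]
    n <- nrow(M)
    w <- if (!is.null(m$weights)) m$weights[[ch]] else rep(1, n)
    masked <- if (!is.null(m$masked)) m$masked[[ch]] else Matrix::rowSums(.sym_counts(M)) == 0
    tri <- Matrix::summary(M)
    if (nrow(tri) == 0L)
      return(list(oe = M, diag_mean = rep(NA_real_, n), masked = rep(TRUE, n)))
    bal_x <- tri$x / (w[tri$i] * w[tri$j])
    d <- tri$j - tri$i
    # unmasked bin-pair count per diagonal
    unm <- as.numeric(!masked)
    cum <- cumsum(unm)
    n_pairs <- vapply(0:(n - 1), function(dd) {
      i <- seq_len(n - dd)
      sum(unm[i] * unm[i + dd])
    }, 0)
    sums <- rep(0, n)
    agg <- tapply(bal_x, d, sum)
    sums[as.integer(names(agg)) + 1L] <- agg
    diag_mean <- ifelse(n_pairs > 0, sums / n_pairs, NA_real_)
    oe_x <- bal_x / diag_mean[d + 1L]
    oe <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = oe_x, dims = c(n, n))
    list(oe = oe, diag_mean = diag_mean, masked = masked)
  })
  names(out) <- names(m$matrices)
  out
}
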