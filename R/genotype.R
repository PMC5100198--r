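# Genotype containers and the allele-frequency-weighted genotype coding.

#' Construct a genotype (exogenous) data container
#'
#' Holds the numeric sample-by-column matrix used as the exogenous block of
#' the structural system, together with per-column metadata: SNP records
#' (`id`, `position`, `freq_Q`, `freq_q`, optional `gene`) for coded
#' genotypes, or (`id`, `gene`, `component`) descriptors for functional
#' principal component scores.
#'
#' @param values numeric matrix (samples by columns).
#' @param columns tibble of per-column metadata, one row per column.
#' @param sample_ids optional character vector of sample identifiers.
#' @return object of class `genotype_data`.
#' @export
genotype_data <- function(values, columns = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(columns)) {
    columns <- tibble::tibble(id = colnames(values) %||%
                                paste0("X", seq_len(ncol(values))))
  }
  stopifnot(nrow(columns) == ncol(values))
  if (!is.null(sample_ids)) {
    stopifnot(length(sample_ids) == nrow(values))
    rownames(values) <- sample_ids
  }
  colnames(values) <- columns$id
  structure(list(values = values, columns = tibble::as_tibble(columns),
                 sample_ids = sample_ids %||% rownames(values)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("<genotype_data> ", nrow(x$values), " samples x ", ncol(x$values),
      " columns\n", sep = "")
  print(utils::head(x$columns, 5))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$values)

#' Code genotype calls by allele frequency
#'
#' Converts calls in \{QQ, Qq, qq\} into the frequency-weighted numeric
#' coding used for genotype profiles: `QQ -> 2 P_q`, `Qq -> P_q - P_Q`,
#' `qq -> -2 P_Q`, where `P_Q`, `P_q` are the allele frequencies at the
#' site. Under Hardy-Weinberg equilibrium the coded value has expectation
#' zero. Missing calls are imputed to 0 (the coded-genotype mean).
#'
#' @param calls character matrix (samples by SNPs) with entries `"QQ"`,
#'   `"Qq"`, `"qq"` or `NA`; `"qQ"` is accepted as `"Qq"`.
#' @param freqs data frame with one row per SNP and columns `freq_Q` and
#'   `freq_q` (strictly inside (0, 1), summing to 1); optional columns `id`,
#'   `position`, `gene` are carried into the result.
#' @return a [genotype_data] with the coded matrix and SNP metadata.
#' @examples
#' calls <- matrix(c("QQ", "Qq", "qq"), 3, 1)
#' encode_genotypes(calls, data.frame(freq_Q = 0.5, freq_q = 0.5))$values
#' @export
encode_genotypes <- function(calls, freqs) {
  calls <- as.matrix(calls)
  freqs <- as.data.frame(freqs)
  stopifnot(ncol(calls) == nrow(freqs))
  if (!all(c("freq_Q", "freq_q") %in% names(freqs))) {
    stop("freqs needs columns freq_Q and freq_q", call. = FALSE)
  }
  pQ <- freqs$freq_Q
  pq <- freqs$freq_q
  if (any(pQ <= 0 | pQ >= 1 | pq <= 0 | pq >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(abs(pQ + pq - 1) > 1e-9)) {
    stop("freq_Q + freq_q must equal 1", call. = FALSE)
  }
  known <- c("QQ", "Qq", "qQ", "qq")
  bad <- which(!(calls %in% known) & !is.na(calls), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("unknown genotype call '", calls[bad[1, 1], bad[1, 2]],
         "' at sample ", bad[1, 1], ", SNP ", bad[1, 2], call. = FALSE)
  }
  coded <- matrix(0, nrow(calls), ncol(calls))
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j]
    coded[, j] <- dplyr::case_when(
      v == "QQ" ~ 2 * pq[j],
      v %in% c("Qq", "qQ") ~ pq[j] - pQ[j],
      v == "qq" ~ -2 * pQ[j],
      TRUE ~ 0  # missing: mean-imputed under the coding
    )
  }
  columns <- tibble::tibble(
    id = freqs$id %||% colnames(calls) %||% paste0("snp", seq_len(ncol(calls))),
    position = freqs$position %||% NA_integer_,
    freq_Q = pQ, freq_q = pq,
    gene = freqs$gene %||% NA_character_)
  genotype_data(coded, columns = columns, sample_ids = rownames(calls))
}

#' Inverse rank normal transformation
#'
#' Maps a numeric vector to normal scores via its ranks using the Blom
#' offset: `qnorm((rank - 3/8) / (n + 1/4))`. The result depends only on the
#' ranks, so any monotone transform of the input yields the same output.
#' Ties share the average rank.
#'
#' @param x numeric vector, `length(x) >= 2`, not constant.
#' @param offset rank offset constant (Blom's 3/8 by default).
#' @return numeric vector of normal scores.
#' @export
inverse_rank_normal <- function(x, offset = 3 / 8) {
  stopifnot(length(x) >= 2)
  if (length(unique(x[!is.na(x)])) < 2) {
    stop("inverse rank normal transform is undefined for a constant column",
         call. = FALSE)
  }
  n <- sum(!is.na(x))
  r <- rank(x, na.last = "keep", ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}
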