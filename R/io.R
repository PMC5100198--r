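# Readers and writers: VCF / dosage genotypes, phenotype tables, gene maps
# (TSV or BED), and the network edge-list format.

#' Read genotypes from VCF or a dosage table
#'
#' VCF input (via the vcfR parser) keeps biallelic SNVs only; multiallelic
#' sites are skipped with a warning and monomorphic sites are excluded with
#' a warning. Genotype calls are mapped with the reference allele as `Q` and
#' the alternate allele as `q` (`0/0 -> QQ`, `0/1 -> Qq`, `1/1 -> qq`;
#' phased separators accepted). Allele frequencies are estimated from the
#' sample by allele counting unless the file provides an `AF` INFO field.
#' Dosage input is a TSV with a `sample_id` column and one integer column
#' (0/1/2 alternate-allele count, NA allowed) per SNP.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @param encode return a coded [genotype_data] (default); `FALSE` returns
#'   the raw list with `calls`, `freqs`, and (for dosage input) `dosage`.
#' @return a [genotype_data], or the raw list when `encode = FALSE`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           encode = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
    else "dosage"
  }
  raw <- if (format == "vcf") read_vcf_calls(path) else read_dosage_calls(path)
  raw <- drop_monomorphic(raw)
  if (!encode) return(raw)
  gd <- encode_genotypes(raw$calls, raw$freqs)
  gd
}

read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped", call. = FALSE)
  }
  keep <- which(!multi)
  if (length(keep) == 0) stop("no biallelic sites in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  calls_map <- c("0/0" = "QQ", "0|0" = "QQ",
                 "0/1" = "Qq", "0|1" = "Qq", "1/0" = "Qq", "1|0" = "Qq",
                 "1/1" = "qq", "1|1" = "qq",
                 "./." = NA, ".|." = NA, "." = NA)
  bad <- !(gt %in% names(calls_map)) & !is.na(gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unsupported genotype '", gt[w[1], w[2]], "' at record ", w[1],
         call. = FALSE)
  }
  calls <- t(matrix(calls_map[gt], nrow = nrow(gt),
                    dimnames = dimnames(gt)))
  info_af <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "AF")[keep]))
  alt_count <- colSums(rbind((calls == "Qq") * 1, (calls == "qq") * 2),
                       na.rm = TRUE)
  n_called <- colSums(!is.na(calls))
  sample_af <- alt_count / pmax(2 * n_called, 1)
  af <- ifelse(is.na(info_af), sample_af, info_af)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  list(calls = calls,
       freqs = tibble::tibble(id = ids,
                              position = as.integer(fix$POS),
                              freq_Q = 1 - af, freq_q = af,
                              chrom = fix$CHROM))
}

read_dosage_calls <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("dosage table needs a sample_id column", call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  dos <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(dos) <- ids
  if (any(!(dos %in% c(0, 1, 2)) & !is.na(dos))) {
    stop("dosages must be 0, 1 or 2 (alternate-allele count)",
         call. = FALSE)
  }
  calls <- matrix(c("QQ", "Qq", "qq")[dos + 1], nrow(dos),
                  dimnames = dimnames(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  list(calls = calls,
       freqs = tibble::tibble(id = colnames(dos),
                              position = NA_integer_,
                              freq_Q = 1 - af, freq_q = af),
       dosage = dos)
}

drop_monomorphic <- function(raw) {
  mono <- apply(raw$calls, 2, function(v) {
    length(unique(v[!is.na(v)])) < 2
  })
  if (any(mono)) {
    warning(sum(mono), " monomorphic site(s) excluded: ",
            paste(utils::head(raw$freqs$id[mono], 5), collapse = ", "),
            call. = FALSE)
    raw$calls <- raw$calls[, !mono, drop = FALSE]
    raw$freqs <- raw$freqs[!mono, , drop = FALSE]
    if (!is.null(raw$dosage)) {
      raw$dosage <- raw$dosage[, !mono, drop = FALSE]
    }
  }
  raw
}

#' Write a dosage TSV
#'
#' @param dosage integer matrix (0/1/2) with sample rownames, or a calls
#'   matrix of `QQ`/`Qq`/`qq`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dosage <- function(dosage, path) {
  if (is.character(dosage)) {
    dosage <- matrix(match(dosage, c("QQ", "Qq", "qq")) - 1, nrow(dosage),
                     dimnames = dimnames(dosage))
  }
  df <- tibble::as_tibble(dosage, .name_repair = "minimal")
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(dosage) %||%
                     paste0("S", seq_len(nrow(dosage)))), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with a header row; the sample-id column is either named `sample_id`
#' or taken to be the first column.
#'
#' @param path file path.
#' @return tibble with a character `sample_id` column followed by numeric
#'   phenotype columns.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  dplyr::relocate(df, "sample_id")
}

#' Read a gene map (TSV or BED)
#'
#' TSV form: two columns, `snp_id` and `gene_id` (header optional as long
#' as the columns are in that order). BED form (detected by extension):
#' 0-based half-open intervals converted to 1-based inclusive; SNPs are
#' assigned to genes by position.
#'
#' @param path file path.
#' @param snps optional SNP tibble (`id`, `position`, `chrom`) required for
#'   BED input.
#' @return tibble with `snp_id` and `gene_id`.
#' @export
read_gene_map <- function(path, snps = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(bed) < 4) stop("BED gene file needs 4 columns", call. = FALSE)
    names(bed)[1:4] <- c("chrom", "start", "end", "gene_id")
    bed$start <- bed$start + 1L  # to 1-based inclusive
    if (is.null(snps)) stop("BED input needs the SNP table", call. = FALSE)
    hits <- purrr::pmap(bed[, c("chrom", "start", "end", "gene_id")],
      function(chrom, start, end, gene_id) {
        sel <- snps$position >= start & snps$position <= end
        if ("chrom" %in% names(snps)) sel <- sel & snps$chrom == chrom
        tibble::tibble(snp_id = snps$id[sel], gene_id = gene_id)
      })
    return(dplyr::bind_rows(hits))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(df))) {
    names(df)[1:2] <- c("snp_id", "gene_id")
  }
  df[, c("snp_id", "gene_id")]
}

#' Attach gene assignments to genotype columns
#'
#' @param X a [genotype_data].
#' @param gene_map tibble with `snp_id` and `gene_id`.
#' @return `X` with the `gene` column of its metadata filled in; columns
#'   without an assignment keep `NA`.
#' @export
assign_genes <- function(X, gene_map) {
  stopifnot(inherits(X, "genotype_data"))
  map <- stats::setNames(gene_map$gene_id, gene_map$snp_id)
  X$columns$gene <- unname(map[X$columns$id])
  X
}

#' Write / read a network edge list
#'
#' The edge-list TSV has columns `source`, `target`, `edge_type`,
#' `coefficient`, `p_value`, `stability` (missing quantities are written as
#' NA). An empty network writes a header-only file.
#'
#' @param edges tibble with at least `from`, `to`, `type`, `coefficient`
#'   (as produced by [support_edges()] or [network_edges()]).
#' @param path file path.
#' @return `write_network` returns the path invisibly; `read_network`
#'   returns the edge tibble with the internal column names (`from`, `to`,
#'   `type`, ...).
#' @export
write_network <- function(edges, path) {
  out <- tibble::tibble(
    source = edges[["from"]] %||% character(0),
    target = edges[["to"]] %||% character(0),
    edge_type = edges[["type"]] %||% character(0),
    coefficient = edges[["coefficient"]] %||% numeric(0),
    p_value = edges[["p_value"]] %||% rep(NA_real_, nrow(edges)),
    stability = edges[["stability"]] %||% rep(NA_real_, nrow(edges)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          source = readr::col_character(),
                          target = readr::col_character(),
                          edge_type = readr::col_character()))
  tibble::tibble(from = df$source, to = df$target, type = df$edge_type,
                 coefficient = df$coefficient, p_value = df$p_value,
                 stability = df$stability)
}

#' Edge list of a fitted network with test annotations
#'
#' @param fit a `sem_fit`.
#' @param tests optional tibble from [test_all_paths()] (p-values merged by
#'   outcome/causal).
#' @param stability optional tibble from [stability_selection()].
#' @param level `"column"` or `"gene"`.
#' @return tibble `from`, `to`, `type` (`phenotype->phenotype` edges typed
#'   `"phenotype"`, genotype edges `"genotype"`), `coefficient`, `p_value`,
#'   `stability`.
#' @export
network_edges <- function(fit, tests = NULL, stability = NULL,
                          level = c("column", "gene")) {
  level <- match.arg(level)
  edges <- support_edges(fit, level = level)
  if (!is.null(tests)) {
    edges <- dplyr::left_join(
      edges, dplyr::select(tests, "outcome", "causal", "p_value"),
      by = c(to = "outcome", from = "causal"))
  }
  if (!is.null(stability)) {
    edges <- dplyr::left_join(
      edges, dplyr::select(stability, "from", "to", "stability"),
      by = c("from", "to"))
  }
  edges
}
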