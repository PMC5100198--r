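`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Accept a matrix or data frame of phenotypes; a `sample_id` column is
# dropped (kept as rownames).
phenotype_values <- function(Y) {
  if (is.matrix(Y)) {
    storage.mode(Y) <- "double"
    return(Y)
  }
  if (inherits(Y, "data.frame")) {
    df <- as.data.frame(Y)
    if ("sample_id" %in% names(df)) {
      ids <- as.character(df$sample_id)
      df$sample_id <- NULL
      m <- as.matrix(df)
      rownames(m) <- ids
    } else {
      m <- as.matrix(df)
    }
    if (!is.numeric(m)) stop("phenotype columns must be numeric",
                             call. = FALSE)
    return(m)
  }
  stop("Y must be a matrix or data frame", call. = FALSE)
}

# Accept a matrix, data frame, or genotype_data for the exogenous block.
exogenous_values <- function(X) {
  if (inherits(X, "genotype_data")) return(X$values)
  phenotype_values(X)
}

exogenous_blocks <- function(X, exo_names) {
  if (inherits(X, "genotype_data") && "gene" %in% names(X$columns) &&
      !all(is.na(X$columns$gene))) {
    idx <- seq_along(exo_names)
    split(idx, X$columns$gene[idx])
  } else {
    NULL
  }
}

check_alignment <- function(Y, X) {
  yid <- sample_ids_of(Y)
  xid <- sample_ids_of(X)
  if (!is.null(yid) && !is.null(xid)) {
    if (length(yid) != length(xid) || any(yid != xid)) {
      bad <- union(setdiff(yid, xid), setdiff(xid, yid))
      stop("sample ids of phenotypes and genotypes do not align",
           if (length(bad)) paste0(": ", paste(utils::head(bad, 10),
                                               collapse = ", ")) else "",
           call. = FALSE)
    }
  } else if (nrow_of(Y) != nrow_of(X)) {
    stop("phenotype and genotype tables have different numbers of samples",
         call. = FALSE)
  }
  invisible(TRUE)
}

sample_ids_of <- function(x) {
  if (inherits(x, "genotype_data")) return(x$sample_ids)
  if (inherits(x, "data.frame") && "sample_id" %in% names(x)) {
    return(as.character(x$sample_id))
  }
  rn <- rownames(x)
  if (!is.null(rn) && !identical(rn, as.character(seq_len(nrow(x))))) rn
  else NULL
}

nrow_of <- function(x) {
  if (inherits(x, "genotype_data")) nrow(x$values) else nrow(x)
}
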