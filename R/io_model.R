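#' Read a GMT gene-set file
#'
#' GMT ("gene matrix transposed") is the standard tab-separated gene-set
#' format: one set per line as `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Used both for protein-interaction network modules and for GO sets.
#'
#' @param path Path to a GMT file.
#' @param provenance Optional tag describing the origin of the sets (for
#'   example `"physical"` or `"functional"` network), stored as an attribute.
#' @return A named list of character vectors of gene ids (order-preserving,
#'   duplicates within a set removed with a warning), class
#'   `"module_collection"`, with attributes `description` (named character)
#'   and `provenance`.
#' @export
read_gmt <- function(path, provenance = NA_character_) {
  lines <- readLines(path)
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) {
      stop(sprintf("GMT parse error at line %d: empty line", i))
    }
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L || !nzchar(fields[[1]])) {
      stop(sprintf("GMT parse error at line %d: need name, description and >=1 gene", i))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("GMT parse error at line %d: no gene ids", i))
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate gene ids removed", i, fields[[1]]))
      genes <- unique(genes)
    }
    sets[[fields[[1]]]] <- genes
    descs[[fields[[1]]]] <- fields[[2]]
  }
  structure(sets, description = descs, provenance = provenance,
            class = c("module_collection", "list"))
}

#' Write a module collection to a GMT file
#'
#' @param modules Named list of character vectors (as from [read_gmt()]).
#' @param path Output path.
#' @param description Optional named character of descriptions; defaults to the
#'   `description` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path, description = NULL) {
  if (is.null(description)) description <- attr(modules, "description")
  lines <- vapply(names(modules), function(nm) {
    desc <- if (!is.null(description) && nm %in% names(description)) description[[nm]] else "na"
    paste(c(nm, desc, modules[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Minor allele frequency from dosages
#'
#' Folded allele frequency `min(f, 1 - f)` with `f = mean(dosage)/2` over
#' non-missing entries. Missing dosages are excluded (never imputed) so the
#' MAF reflects observed alleles only.
#'
#' @param dosages Numeric vector of alternate-allele counts in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(dosages) {
  obs <- dosages[!is.na(dosages)]
  if (length(obs) == 0L) stop("MAF undefined: all dosages missing")
  if (any(!obs %in% c(0, 1, 2))) stop("dosages must be in {0, 1, 2, NA}")
  f <- mean(obs) / 2
  min(f, 1 - f)
}

#' Align multiple sample-indexed tables on their common samples
#'
#' Takes any number of objects carrying sample ids (vectors with names,
#' matrices/data.frames with sample rows or columns, square kinship matrices)
#' and subsets all of them to the intersection of sample ids, in the order
#' those ids appear in the first object. Square matrices whose row and column
#' names are both sample ids (kinship) are subset on both margins.
#'
#' @param ... Named objects to align. Each must have sample ids as `names`
#'   (vectors), `rownames` (matrices / data.frames with samples in rows), or
#'   `colnames` when `samples_in = "cols"` entries name it.
#' @param samples_in Character vector (recycled) saying where sample ids live
#'   for each object: `"rows"` (default) or `"cols"`.
#' @return A list with the aligned objects, plus attributes `samples` (the
#'   common ordered ids) and `dropped` (named integer: ids dropped per input).
#' @export
align_samples <- function(..., samples_in = "rows") {
  objs <- list(...)
  if (length(objs) < 1L) stop("no tables to align")
  samples_in <- rep_len(samples_in, length(objs))
  ids_of <- function(x, where) {
    if (is.null(dim(x))) names(x)
    else if (where == "cols") colnames(x)
    else rownames(x)
  }
  id_list <- Map(ids_of, objs, samples_in)
  if (any(vapply(id_list, is.null, logical(1)))) {
    stop("every table must carry sample ids")
  }
  common <- Reduce(intersect, id_list[-1], id_list[[1]])
  if (length(common) == 0L) stop("sample alignment error: empty intersection")
  take <- function(x, where) {
    sq <- !is.null(dim(x)) && nrow(x) == ncol(x) &&
      !is.null(rownames(x)) && !is.null(colnames(x)) &&
      all(common %in% rownames(x)) && all(common %in% colnames(x)) &&
      setequal(rownames(x), colnames(x))
    if (is.null(dim(x))) x[common]
    else if (sq) x[common, common, drop = FALSE]
    else if (where == "cols") x[, common, drop = FALSE]
    else x[common, , drop = FALSE]
  }
  out <- Map(take, objs, samples_in)
  names(out) <- names(objs)
  dropped <- vapply(id_list, function(ids) length(setdiff(ids, common)), integer(1))
  names(dropped) <- names(objs)
  structure(out, samples = common, dropped = dropped)
}

#' Read genotype dosages from a VCF file
#'
#' Parses GT fields of a (biallelic, unphased or phased) VCF into a variant x
#' sample dosage matrix plus a variant table with per-variant MAF.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A list with `variants` (data.frame: variant_id, chrom, pos, ref,
#'   alt, maf) and `dosages` (numeric matrix, variants x samples, NA for
#'   missing genotypes).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dos <- gt_to_dosage(gt)
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, "/", fix$ALT), ids)
  }
  rownames(dos) <- ids
  maf <- apply(dos, 1L, compute_maf)
  list(
    variants = data.frame(
      variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, maf = maf,
      stringsAsFactors = FALSE
    ),
    dosages = dos
  )
}

# "0/1", "1|1", "./." ... -> 0,1,2,NA
gt_to_dosage <- function(gt) {
  alt_count <- function(s) {
    if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  out <- vapply(gt, alt_count, numeric(1))
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a tab-separated table with a header
#'
#' @param path Path to a TSV file.
#' @param rownames_col Optional column name to use as rownames (dropped from
#'   the returned columns).
#' @return A data.frame.
#' @export
read_tsv <- function(path, rownames_col = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE),
                      stringsAsFactors = FALSE)
  if (!is.null(rownames_col)) {
    rownames(df) <- as.character(df[[rownames_col]])
    df[[rownames_col]] <- NULL
  }
  df
}

#' Write a table as TSV
#'
#' @param x data.frame or matrix.
#' @param path Output path.
#' @param rownames_col If non-NULL, write rownames as a first column with this
#'   name.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, rownames_col = NULL) {
  x <- as.data.frame(x)
  if (!is.null(rownames_col)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_col), x)
  }
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square kinship matrix from TSV
#'
#' Expects sample ids as both the header row and the first column.
#'
#' @param path Path to the kinship TSV.
#' @return Numeric symmetric matrix with sample dimnames.
#' @export
read_kinship <- function(path) {
  df <- read_tsv(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m))) {
    stop("kinship matrix must be square with matching sample ids")
  }
  m[ids, ids]
}

#' Clip p-values into a numerically safe open-unit interval
#'
#' p-values are clipped to `[1e-300, 1]` on ingestion so downstream z-score
#' transforms stay finite.
#'
#' @param p Numeric vector.
#' @return Clipped vector.
#' @export
clip_p <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  pmin(pmax(p, 1e-300), 1)
}

#' Canonical rare-variant functional categories
#'
#' The ten functional categories into which rare variants are split for the
#' category-wise set tests.
#'
#' @return Character vector of the 10 category labels.
#' @export
rva_categories <- function() {
  c("synonymous", "missense", "plof", "promoter_CAGE", "promoter_DHS",
    "enhancer_CAGE", "enhancer_DHS", "upstream", "downstream", "UTR")
}

#' Construct a gene-score table
#'
#' The lingua franca between pipeline stages: one row per
#' (gene, trait, source, category) with a p-value, an optional signed effect
#' size and the number of units (variants or samples) behind the score.
#'
#' @param gene_id,trait,source,category,p,beta,n_units Column vectors
#'   (recycled to a common length). `source` is one of GWAS, TWAS, RVA, CMA;
#'   `category` one of the RVA categories or `"none"`.
#' @return data.frame with class `"gene_score_table"`; p clipped via
#'   [clip_p()].
#' @export
gene_score_table <- function(gene_id, trait, source, category = "none",
                             p, beta = NA_real_, n_units = NA_integer_) {
  df <- data.frame(gene_id = gene_id, trait = trait, source = source,
                   category = category, p = clip_p(p), beta = beta,
                   n_units = n_units, stringsAsFactors = FALSE)
  ok_src <- c("GWAS", "TWAS", "RVA", "CMA")
  if (!all(df$source %in% ok_src)) stop("unknown source label")
  if (!all(df$category %in% c(rva_categories(), "none"))) stop("unknown category label")
  if (anyDuplicated(df[c("gene_id", "trait", "source", "category")])) {
    stop("(gene_id, trait, source, category) rows must be unique")
  }
  class(df) <- c("gene_score_table", "data.frame")
  df
}
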