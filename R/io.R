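#' @keywords internal
"_PACKAGE"

# separator from file extension: .csv -> comma, anything else -> tab
.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a beta-value methylation matrix
#'
#' Reads a CpG-by-sample matrix of methylation beta-values from a delimited
#' text file (first column probe ids, header row sample ids). Beta-values are
#' the methylated-signal fraction and must lie in \[0, 1\]; values outside the
#' range raise an error naming the offending probe and sample.
#'
#' @param path Path to a TSV (or CSV, by extension) file.
#' @param missing_token String representing missing values (default `"NA"`).
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @export
read_beta_matrix <- function(path, missing_token = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids: ", paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  raw[raw == missing_token] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(probe_ids, sample_ids)))
  bad_parse <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad_parse) > 0)
    stop("non-numeric beta-value at probe ", probe_ids[bad_parse[1, 1]],
         ", sample ", sample_ids[bad_parse[1, 2]])
  out <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(out) > 0)
    stop("beta-value out of [0,1] at probe ", probe_ids[out[1, 1]],
         ", sample ", sample_ids[out[1, 2]], " (value ", vals[out[1, , drop = FALSE]], ")")
  vals
}

#' Write a beta-value matrix
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path (TSV unless the extension is `.csv`).
#' @param id_column Name of the first (probe id) column.
#' @export
write_beta_matrix <- function(beta, path, id_column = "probe_id") {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- data.frame(rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.cgi_levels <- c("island", "shore_north", "shore_south",
                 "shelf_north", "shelf_south", "open_sea")

# Illumina manifest dialect -> internal six-level CGI vocabulary
.cgi_map <- c(
  "Island"  = "island",  "island"      = "island",
  "N_Shore" = "shore_north", "S_Shore" = "shore_south",
  "N_Shelf" = "shelf_north", "S_Shelf" = "shelf_south",
  "shore_north" = "shore_north", "shore_south" = "shore_south",
  "shelf_north" = "shelf_north", "shelf_south" = "shelf_south",
  "open_sea" = "open_sea", "OpenSea" = "open_sea"
)

#' Read a 450k-style probe annotation manifest
#'
#' Accepts a manifest-like CSV/TSV with columns for the probe id, chromosome,
#' position, semicolon-separated gene names, relation to the nearest CpG
#' island, and (optionally) the 50-mer probe sequence. Both Illumina column
#' names (`IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`,
#' `Relation_to_UCSC_CpG_Island`, `AlleleA_ProbeSeq`) and the internal names
#' used by [write_probe_annotation()] are recognised. An empty CGI relation
#' maps to `open_sea`. Only autosomes ("1".."22") are accepted: the analysis
#' is restricted to autosomal CpGs by construction.
#'
#' @param path Path to the manifest file.
#' @return A data.frame with columns `probe_id`, `chromosome`, `position`,
#'   `gene_names` (semicolon-separated, possibly empty), `cgi_relation`
#'   (factor over the six island/shore/shelf/open-sea labels) and
#'   `probe_sequence` (may be `NA`).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% colnames(df)) return(df[[nm]])
    NULL
  }
  probe_id <- pick("IlmnID", "probe_id")
  chromosome <- pick("CHR", "chromosome")
  position <- pick("MAPINFO", "position")
  genes <- pick("UCSC_RefGene_Name", "gene_names")
  cgi <- pick("Relation_to_UCSC_CpG_Island", "cgi_relation")
  seqs <- pick("AlleleA_ProbeSeq", "probe_sequence")
  if (is.null(probe_id) || is.null(chromosome) || is.null(position))
    stop("manifest must provide probe id, chromosome and position columns")
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  bad_chr <- setdiff(unique(chromosome), as.character(1:22))
  if (length(bad_chr) > 0)
    stop("unknown chromosome label(s): ", paste(bad_chr, collapse = ", "),
         " (autosomes \"1\"..\"22\" expected)")
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1))
    stop("positions must be integers >= 1")
  if (is.null(genes)) genes <- rep("", length(probe_id))
  genes[is.na(genes)] <- ""
  if (is.null(cgi)) cgi <- rep("", length(probe_id))
  cgi[is.na(cgi) | cgi == ""] <- "open_sea"
  mapped <- unname(.cgi_map[cgi])
  if (any(is.na(mapped)))
    stop("unknown CGI relation label(s): ",
         paste(unique(cgi[is.na(mapped)]), collapse = ", "))
  if (!is.null(seqs)) {
    seqs[seqs == ""] <- NA_character_
    has <- !is.na(seqs)
    if (any(nchar(seqs[has]) != 50L))
      stop("probe sequences must be 50-mers; offending probe: ",
           probe_id[has][which(nchar(seqs[has]) != 50L)[1]])
    if (any(grepl("[^ACGT]", seqs[has])))
      stop("probe sequences must be over {A,C,G,T}; offending probe: ",
           probe_id[has][which(grepl("[^ACGT]", seqs[has]))[1]])
  } else {
    seqs <- rep(NA_character_, length(probe_id))
  }
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, gene_names = genes,
             cgi_relation = factor(mapped, levels = .cgi_levels),
             probe_sequence = seqs, stringsAsFactors = FALSE)
}

#' Write a probe annotation table (manifest dialect)
#'
#' @param annotation Data.frame as returned by [read_probe_annotation()].
#' @param path Output path.
#' @export
write_probe_annotation <- function(annotation, path) {
  df <- data.frame(IlmnID = annotation$probe_id,
                   CHR = annotation$chromosome,
                   MAPINFO = annotation$position,
                   UCSC_RefGene_Name = annotation$gene_names,
                   Relation_to_UCSC_CpG_Island = as.character(annotation$cgi_relation),
                   AlleleA_ProbeSeq = ifelse(is.na(annotation$probe_sequence),
                                             "", annotation$probe_sequence),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split semicolon-separated gene annotations, de-duplicated per probe
#'
#' @param gene_names Character vector of semicolon-separated gene lists.
#' @return A list of unique gene-symbol character vectors (possibly empty).
#' @export
split_gene_names <- function(gene_names) {
  lapply(strsplit(gene_names, ";", fixed = TRUE),
         function(g) unique(g[g != ""]))
}

#' Probe counts per gene
#'
#' Counts, for every gene in the annotation, the number of distinct probes
#' annotated to it. A probe listing the same gene several times (one entry
#' per transcript in the Illumina manifest) contributes once.
#'
#' @param annotation Probe annotation data.frame.
#' @return Data.frame with columns `gene` and `n_probes`.
#' @export
gene_probe_counts <- function(annotation) {
  genes <- split_gene_names(annotation$gene_names)
  tab <- table(unlist(genes))
  data.frame(gene = names(tab), n_probes = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one gene symbol per field.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || all(f[-(1:2)] == ""))
      stop("malformed GMT record (empty gene set) at line ", i)
    members <- unique(f[-(1:2)])
    members <- members[members != ""]
    if (length(members) == 0) stop("malformed GMT record at line ", i)
    if (f[1] %in% names(sets)) stop("duplicate gene-set name at line ", i, ": ", f[1])
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene symbol vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample covariate table
#'
#' First column is the sample id; remaining columns are covariates. Columns
#' read as character are kept as factors (categorical covariates expand to
#' dummy variables in the design matrix), numeric columns as numeric.
#'
#' @param path TSV/CSV file.
#' @return Data.frame with a `sample_id` column.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, stringsAsFactors = TRUE,
                          quote = "", comment.char = "")
  colnames(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df
}

#' Write a results table as TSV with scientific-notation p-values
#'
#' Column order is preserved as given; columns whose name starts with `p`
#' (e.g. `p`, `p_meta`, `p_b2`) are formatted in scientific notation.
#'
#' @param records Data.frame of results.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  out <- records
  pcols <- grep("^p($|_)", colnames(out))
  for (j in pcols) out[[j]] <- format(out[[j]], digits = 6, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag probes with low call rate
#'
#' Probes with fewer than `min_callrate` non-missing samples are flagged;
#' the pipeline reports them but (as with raw-data call-rate rules applied
#' upstream of normalized betas) does not silently drop them.
#'
#' @param beta Beta-value matrix.
#' @param min_callrate Minimum fraction of non-missing samples (default 0.9).
#' @return Character vector of flagged probe ids.
#' @export
flag_low_callrate <- function(beta, min_callrate = 0.9) {
  cr <- rowMeans(!is.na(beta))
  rownames(beta)[cr < min_callrate]
}
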