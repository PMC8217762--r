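#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a sequence set. The record
#' id is the header token up to the first whitespace; everything after it is
#' kept as the description. Sequences are uppercased and restricted to the 20
#' canonical amino acids plus `X` (how `X` is treated is up to the consumer:
#' [molecular_weight()] assigns it the average residue mass,
#' [isoelectric_point()] ignores it).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`
#'   (one row per record, input order preserved).
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("empty FASTA file: ", path)
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", .aa_alphabet), seqs)
  if (any(bad)) {
    stop("non-canonical residues (outside 20 amino acids + X) in: ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = unname(ids), description = unname(desc),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"

#' Write a sequence set to FASTA
#'
#' @param seqs Data frame with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  hdr <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  aa <- Biostrings::AAStringSet(seqs$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into a named character vector of
#' equal-length aligned rows. `.` gap characters are normalised to `-`.
#'
#' @param path Path to the alignment.
#' @param format `"fasta"` or `"clustal"`.
#' @return Named character vector (names = taxa, values = aligned rows),
#'   validated by [as_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(aln)
  as_alignment(rows)
}

#' Validate an alignment
#'
#' Checks the alignment invariants (>= 2 rows, unique taxon names, all rows
#' the same length) and normalises `.` gaps to `-`.
#'
#' @param rows Named character vector of aligned sequences.
#' @return The validated (normalised, uppercased) alignment.
#' @export
as_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by taxon")
  }
  if (length(rows) < 2L) stop("alignment needs >= 2 rows")
  if (anyDuplicated(names(rows))) {
    stop("duplicate taxa: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  }
  rows[] <- toupper(gsub(".", "-", rows, fixed = TRUE))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  rows
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Column-index based parser for the `hmmsearch --domtblout` format:
#' `#` lines are comments; fields are whitespace-separated; target name is
#' column 1, query accession column 5, full-sequence E-value column 7,
#' full-sequence bit score column 8, independent E-value column 13, envelope
#' from/to columns 20-21 (1-based inclusive residue coordinates).
#'
#' @param path Path to a domtblout file.
#' @return Data frame with columns `target_id`, `query_accession`,
#'   `full_seq_evalue`, `full_seq_score`, `domain_ievalue`, `env_from`,
#'   `env_to`; one row per domain line.
#' @export
read_domtbl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(target_id = character(), query_accession = character(),
                      full_seq_evalue = double(), full_seq_score = double(),
                      domain_ievalue = double(), env_from = integer(),
                      env_to = integer(), stringsAsFactors = FALSE))
  }
  parse_line <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 21L) {
      stop("domtblout line ", i, ": expected >= 21 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(7, 8, 13)]))
    ints <- suppressWarnings(as.integer(f[c(20, 21)]))
    if (anyNA(num) || anyNA(ints)) {
      stop("domtblout line ", i, ": malformed numeric field")
    }
    list(target_id = f[1], query_accession = f[5],
         full_seq_evalue = num[1], full_seq_score = num[2],
         domain_ievalue = num[3], env_from = ints[1], env_to = ints[2])
  }
  rows <- lapply(idx, parse_line)
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  if (any(out$env_from > out$env_to)) stop("env_from > env_to in domtblout")
  if (any(out$full_seq_evalue < 0) || any(out$domain_ievalue < 0)) {
    stop("negative E-value in domtblout")
  }
  out
}

#' Read a gene coordinate table
#'
#' Tab-separated with a header; required columns `gene_id`, `family`,
#' `chromosome`, `start`, `end` (1-based inclusive bp); optional `strand`
#' (read but ignored by downstream analyses — the tandem rule is
#' strand-agnostic). Row order is preserved; sorting/indexing is done by the
#' consumer ([assign_order_index()]).
#'
#' @param path Path to the TSV.
#' @return Data frame of gene loci.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "family", "chromosome", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("gene table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-integer start/end in gene table")
  }
  if (any(df$start > df$end)) stop("start > end in gene table")
  df
}

#' Read an ortholog presence table
#'
#' Long-format TSV with header columns `gene_id`, `species`, `has_ortholog`
#' (0/1 or TRUE/FALSE), pivoted into a genes x species logical presence
#' matrix with species columns in the fixed phylostratigraphic order.
#'
#' @param path Path to the TSV.
#' @param species Ordered reference species (most to least related);
#'   defaults to the four-species ladder used throughout
#'   (zebrafish, sea urchin, nematode, yeast).
#' @return Logical matrix, rows = genes, columns = `species`.
#' @export
read_ortholog_table <- function(path, species = phylostrat_species()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "species", "has_ortholog")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("ortholog table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  unknown <- setdiff(unique(df$species), species)
  if (length(unknown) > 0L) {
    stop("unknown species in ortholog table: ",
         paste(unknown, collapse = ", "))
  }
  genes <- unique(df$gene_id)
  m <- matrix(FALSE, nrow = length(genes), ncol = length(species),
              dimnames = list(genes, species))
  m[cbind(df$gene_id, df$species)] <- as.logical(as.integer(df$has_ortholog))
  m
}

#' Read a normalised expression matrix
#'
#' TSV with a header: first column gene ids, remaining columns one sample
#' each, values normalised log2 intensities.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rows = genes, columns = samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs gene ids plus >= 1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("missing values in expression matrix")
  m
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so the rest of
#' the pipeline deals only in `phylo` objects. Internal-node labels carry
#' bootstrap supports when present.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' Export gene loci as BED
#'
#' Converts the 1-based inclusive coordinates used throughout the package to
#' BED's 0-based half-open convention at the boundary.
#'
#' @param loci Gene table (see [read_gene_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chromosome,
                    chromStart = loci$start - 1L,
                    chromEnd = loci$end,
                    name = loci$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
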