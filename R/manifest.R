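#' Construct a genome manifest
#'
#' A genome manifest is the universe of genes being clustered: one row per
#' protein-coding gene, carrying the genome it belongs to and its sequence
#' length in amino-acid residues. Genes encoded on plasmids are listed under
#' their host genome, so that per-genome totals (`N_genes`) count all
#' protein-coding genes of the organism.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param genome_id character vector, same length, naming the source genome.
#' @param length integer vector of protein lengths (residues), all >= 1.
#'
#' @return A `data.table` of class `genome_manifest` with columns
#'   `gene_id`, `genome_id`, `length`, sorted by `gene_id`.
#' @export
#' @examples
#' genome_manifest(c("a1", "a2", "b1"), c("A", "A", "B"), c(120L, 300L, 95L))
genome_manifest <- function(gene_id, genome_id, length) {
  gene_id <- as.character(gene_id)
  genome_id <- as.character(genome_id)
  length <- as.integer(length)
  if (!(length(gene_id) == length(genome_id) &&
        length(gene_id) == length(length))) {
    stop("gene_id, genome_id and length must have equal lengths")
  }
  if (length(gene_id) == 0L) stop("a manifest must contain at least one gene")
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id in manifest: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyNA(length) || any(length < 1L)) {
    stop("all sequence lengths must be positive integers")
  }
  m <- data.table::data.table(gene_id = gene_id, genome_id = genome_id,
                              length = length)
  data.table::setkeyv(m, "gene_id")
  data.table::setattr(m, "class", c("genome_manifest", class(m)))
  m[]
}

#' @export
print.genome_manifest <- function(x, ...) {
  cat(sprintf("genome_manifest: %d genes across %d genomes\n",
              nrow(x), length(unique(x$genome_id))))
  NextMethod()
}

#' Genomes present in a manifest
#' @param manifest a [genome_manifest()].
#' @return sorted character vector of genome ids.
#' @export
manifest_genomes <- function(manifest) sort(unique(manifest$genome_id))

#' Read a genome manifest from disk
#'
#' Two layouts are accepted: a single tab-separated file with a header line
#' `gene_id  genome_id  length`, or a directory of per-genome protein FASTA
#' files (one file per genome; the genome id is the file name without its
#' `.fa`/`.faa`/`.fasta` extension, the gene id is the first
#' whitespace-delimited token of each header, and the length is the sequence
#' length).
#'
#' @param path path to a manifest TSV or a directory of FASTA files.
#' @return a [genome_manifest()].
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|faa|fasta)$", full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files (*.fa, *.faa, *.fasta) in ", path)
    parts <- lapply(files, function(f) {
      seqs <- Biostrings::readAAStringSet(f)
      ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
      data.table::data.table(
        gene_id = ids,
        genome_id = sub("\\.(fa|faa|fasta)$", "", basename(f)),
        length = Biostrings::width(seqs))
    })
    m <- data.table::rbindlist(parts)
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    m <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("gene_id", "genome_id")))
    need <- c("gene_id", "genome_id", "length")
    if (!all(need %in% names(m))) {
      stop("manifest TSV must have columns: ", paste(need, collapse = ", "))
    }
  }
  genome_manifest(m$gene_id, m$genome_id, m$length)
}

#' Write a manifest TSV
#' @param manifest a [genome_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.table::as.data.table(manifest)[order(gene_id)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
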