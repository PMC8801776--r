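# File formats: FASTA via Biostrings, tables as TSV, trees as Newick.

#' Read protein or CDS sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"protein"` or `"dna"`.
#' @export
write_fasta <- function(seqs, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path TSV file with a header row.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all artifacts of a synthetic genome to a directory
#'
#' Emits protein and CDS FASTA, annotation/segment-map/ground-truth
#' TSVs, in the layout expected by the real-mode readers.
#'
#' @param genome A `synthetic_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$proteins, file.path(dir, "proteins.faa"), "protein")
  write_fasta(genome$cds, file.path(dir, "cds.fna"), "dna")
  write_tsv(genome$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(genome$segment_map, file.path(dir, "segments.tsv"))
  write_tsv(genome$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(genome$truth$duplicate_pairs,
            file.path(dir, "truth_duplicate_pairs.tsv"))
  write_tsv(data.frame(chromosome = names(genome$chromosome_lengths),
                       length = unname(genome$chromosome_lengths)),
            file.path(dir, "chromosomes.tsv"))
  invisible(dir)
}
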