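#' Build a species-annotated marker alignment
#'
#' A marker alignment is the unit every stage of the package consumes: one
#' multiple sequence alignment for a single barcode marker (or a
#' concatenation of markers), with each aligned sequence annotated with the
#' sample it came from and the species that sample belongs to.  It is stored
#' as a tibble with one row per sample and columns `sample_id`, `species`,
#' `marker`, `origin` and `residues`, so the usual dplyr verbs apply.
#'
#' Residues are uppercased on construction and may contain only the four
#' bases, IUPAC ambiguity codes and the gap character `-`.  All sequences
#' must have equal (aligned) length and sample ids must be unique.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param species Character vector of species names (whitespace is
#'   normalized; species are compared by exact name).
#' @param residues Character vector of aligned sequences.
#' @param marker Single marker name (e.g. `"ITS2"`).
#' @param origin Optional character vector of free-text provenance
#'   (cultivar/wild/location); recycled if length 1.
#'
#' @return A tibble of class `marker_alignment`.
#' @examples
#' aln <- marker_alignment(
#'   sample_id = c("s1", "s2"),
#'   species = c("A", "A"),
#'   residues = c("ACGT", "ACGA"),
#'   marker = "demo"
#' )
#' n_columns(aln)
#' @export
marker_alignment <- function(sample_id, species, residues, marker,
                             origin = NA_character_) {
  x <- tibble(
    sample_id = as.character(sample_id),
    species = stringr::str_squish(as.character(species)),
    marker = as.character(marker),
    origin = as.character(origin),
    residues = toupper(as.character(residues))
  )
  validate_marker_alignment(x)
}

validate_marker_alignment <- function(x) {
  required <- c("sample_id", "species", "marker", "origin", "residues")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("marker alignment is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) < 2) {
    abort("a marker alignment needs at least 2 records")
  }
  if (any(is.na(x$sample_id)) || any(!nzchar(x$sample_id))) {
    abort("sample_id must be non-empty")
  }
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(paste0("duplicated sample_id: ", paste(dup, collapse = ", ")))
  }
  lens <- nchar(x$residues)
  if (length(unique(lens)) != 1) {
    ref <- as.integer(names(which.max(table(lens))))
    off <- x$sample_id[lens != ref]
    abort(paste0(
      "aligned sequences must all have the same length; offending records: ",
      paste(off, collapse = ", ")
    ))
  }
  bad <- !grepl(paste0("^[", paste(c(.BASES, .AMBIG), collapse = ""), "-]*$"),
                x$residues)
  if (any(bad)) {
    abort(paste0(
      "residues outside the IUPAC nucleotide alphabet in: ",
      paste(x$sample_id[bad], collapse = ", ")
    ))
  }
  class(x) <- c("marker_alignment", class(tibble()))
  x
}

#' Alignment dimensions
#'
#' @param aln A [marker_alignment()].
#' @return `n_columns()` returns the number of alignment columns;
#'   `aln_matrix()` the alignment as a character matrix with samples as rows.
#' @export
n_columns <- function(aln) {
  nchar(aln$residues[1])
}

#' @rdname n_columns
#' @export
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$residues, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- aln$sample_id
  m
}

#' Read an aligned FASTA file with its sample metadata
#'
#' Reads an aligned FASTA (gap character `-`) and a tab-separated metadata
#' table with columns `sample_id`, `species`, `marker` and (optionally)
#' `origin`, and returns the validated [marker_alignment()] for one marker.
#' FASTA record order is preserved.  Every FASTA id must appear in the
#' metadata; lowercase residues are uppercased on read.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the TSV metadata table.
#' @param marker Marker name used to select metadata rows and label the
#'   result.
#' @return A [marker_alignment()].
#' @export
read_marker_alignment <- function(fasta_path, metadata_path, marker) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0) {
    abort(paste0("no sequences in FASTA file: ", fasta_path))
  }
  seqs <- vapply(as.character(dna),
                 function(s) paste(toupper(s), collapse = ""), character(1))
  meta <- read_sample_metadata(metadata_path)
  meta <- dplyr::filter(meta, .data$marker == !!marker)
  missing_ids <- setdiff(names(seqs), meta$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0(
      "FASTA id(s) absent from metadata for marker ", marker, ": ",
      paste(missing_ids, collapse = ", ")
    ))
  }
  meta <- meta[match(names(seqs), meta$sample_id), ]
  marker_alignment(
    sample_id = names(seqs),
    species = meta$species,
    residues = unname(seqs),
    marker = marker,
    origin = meta$origin
  )
}

read_sample_metadata <- function(metadata_path) {
  if (!file.exists(metadata_path)) {
    abort(paste0("metadata file not found: ", metadata_path))
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  needed <- c("sample_id", "species", "marker")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"origin" %in% names(meta)) {
    meta$origin <- NA_character_
  }
  meta$species <- stringr::str_squish(meta$species)
  meta
}

#' Write a marker alignment back to FASTA (and optionally metadata)
#'
#' @param aln A [marker_alignment()].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output TSV path for the sample table.
#' @return `aln`, invisibly.
#' @export
write_marker_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  m <- tolower(aln_matrix(aln))
  dna <- ape::as.DNAbin(m)
  ape::write.FASTA(dna, fasta_path)
  if (!is.null(metadata_path)) {
    readr::write_tsv(
      dplyr::select(as_tibble(aln), "sample_id", "species", "marker", "origin"),
      metadata_path
    )
  }
  invisible(aln)
}

#' Concatenate two marker alignments sample-wise
#'
#' Joins two alignments on their shared samples: for each sample present in
#' both inputs the residues of `a` are followed by those of `b`, giving a
#' combined marker (e.g. ITS2 + psbA-trnH).  Samples missing from either
#' input are dropped -- never padded -- and reported, because combined
#' statistics are only meaningful for samples sequenced for both markers.
#'
#' @param a,b [marker_alignment()] objects.
#' @param joined_name Marker name for the combined alignment; defaults to
#'   `"<a>+<b>"`.
#' @return A [marker_alignment()] with `n_columns(a) + n_columns(b)` columns.
#' @export
concatenate_markers <- function(a, b, joined_name = NULL) {
  joined_name <- joined_name %||% paste0(a$marker[1], "+", b$marker[1])
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) == 0) {
    abort("no samples shared between the two alignments")
  }
  dropped <- setdiff(union(a$sample_id, b$sample_id), shared)
  if (length(dropped) > 0) {
    inform(paste0(
      "concatenate_markers: dropped ", length(dropped),
      " sample(s) missing from one marker: ", paste(dropped, collapse = ", ")
    ))
  }
  a_keep <- a[a$sample_id %in% shared, ]
  b_keep <- b[match(a_keep$sample_id, b$sample_id), ]
  marker_alignment(
    sample_id = a_keep$sample_id,
    species = a_keep$species,
    residues = paste0(a_keep$residues, b_keep$residues),
    marker = joined_name,
    origin = a_keep$origin
  )
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment> ", x$marker[1], ": ", nrow(x), " sequences x ",
      n_columns(x), " columns, ", length(unique(x$species)), " species\n",
      sep = "")
  NextMethod()
}
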