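#' Read a transcript expression table
#'
#' Tab-separated: column 1 transcript id, column 2 gene id, optional
#' column 3 gene symbol (character; empty/NA means no accepted symbol),
#' remaining columns one per sample with the sample ids as header.
#'
#' @param path file path.
#' @return list with `expr` (numeric matrix), `gene_of`, `symbol_ok`
#'   (named logical or NULL).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L) stop("expression table needs transcript, gene and >=1 sample column")
  tid <- as.character(dt[[1L]])
  gid <- as.character(dt[[2L]])
  if (anyDuplicated(tid)) {
    dup <- tid[duplicated(tid)][1L]
    stop("duplicate transcript id in expression table: ", dup)
  }
  has_symbol <- ncol(dt) >= 4L && is.character(dt[[3L]])
  first_sample <- if (has_symbol) 4L else 3L
  expr <- as.matrix(dt[, first_sample:ncol(dt), drop = FALSE])
  if (!is.numeric(expr)) {
    bad <- which(!vapply(dt[first_sample:ncol(dt)], is.numeric, logical(1)))[1L]
    stop("non-numeric expression column: ", names(dt)[first_sample + bad - 1L])
  }
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample id in expression header")
  rownames(expr) <- tid
  gene_of <- stats::setNames(gid, tid)
  symbol_ok <- NULL
  if (has_symbol) {
    sym <- as.character(dt[[3L]])
    symbol_ok <- stats::setNames(!is.na(sym) & nzchar(sym) & sym != ".", tid)
  }
  list(expr = expr, gene_of = gene_of, symbol_ok = symbol_ok)
}

#' Read transcript lengths
#' @param path two-column TSV: transcript id, length in nt (no header or
#'   header `transcript`/`length`).
#' @return named numeric vector.
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) stop("lengths file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L) stop("lengths file needs 2 columns")
  len <- as.numeric(dt[[2L]])
  bad <- which(!is.finite(len) | len <= 0)
  if (length(bad))
    stop("non-positive or missing length at line ", bad[1L] + 1L)
  stats::setNames(len, as.character(dt[[1L]]))
}

#' Read sample class labels (and optional patient pairing)
#'
#' TSV with header columns `sample`, `class` and optionally `patient`.
#' Exactly two distinct class labels are required. When a patient column
#' is present, every patient with one sample of each class contributes a
#' pairing row.
#'
#' @param path file path.
#' @param class_levels optional length-2 vector fixing which label is
#'   class1 (reference/"normal") and which class2 ("tumor").
#' @return list with `class_of` (named character) and `pairing`
#'   (data.frame or NULL) and `class_levels`.
#' @export
read_labels <- function(path, class_levels = NULL) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample", "class")
  if (!all(need %in% names(dt))) stop("labels file needs columns: sample, class")
  if (anyDuplicated(dt$sample)) {
    stop("duplicate sample id in labels: ", dt$sample[duplicated(dt$sample)][1L])
  }
  class_of <- stats::setNames(as.character(dt$class), as.character(dt$sample))
  labs <- sort(unique(class_of))
  if (length(labs) != 2L)
    stop("labels file must contain exactly 2 classes, got ", length(labs),
         ": ", paste(labs, collapse = ", "))
  if (is.null(class_levels)) {
    class_levels <- if (setequal(labs, c("normal", "tumor")))
      c("normal", "tumor") else labs
  }
  pairing <- NULL
  if ("patient" %in% names(dt)) {
    sp <- split(dt, dt$patient)
    rows <- lapply(sp, function(d) {
      s1 <- d$sample[d$class == class_levels[1L]]
      s2 <- d$sample[d$class == class_levels[2L]]
      if (length(s1) == 1L && length(s2) == 1L)
        data.frame(patient = d$patient[1L], class1 = s1, class2 = s2,
                   stringsAsFactors = FALSE)
      else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) pairing <- do.call(rbind, rows)
    if (!is.null(pairing)) rownames(pairing) <- NULL
  }
  list(class_of = class_of, pairing = pairing, class_levels = class_levels)
}

#' Transcript genomic structures
#'
#' Container for per-transcript exon layouts used for mutation overlap and
#' GFF export. Coordinates are GTF-style: 1-based, closed intervals.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#' @return object of class `"TranscriptStructures"`.
#' @export
transcript_structures <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
                %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (any(exons$start > exons$end)) stop("exon start > end")
  if (any(transcripts$start > transcripts$end)) stop("transcript start > end")
  sp <- split(exons, exons$transcript_id)
  for (tid in names(sp)) {
    e <- sp[[tid]][order(sp[[tid]]$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tid)
    tr <- transcripts[transcripts$transcript_id == tid, ]
    if (nrow(tr) && (min(e$start) < tr$start[1L] || max(e$end) > tr$end[1L]))
      stop("transcript span does not cover exons for ", tid)
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "TranscriptStructures")
}

#' Read transcript structures from a GTF file
#'
#' Parses exon features; transcript spans are the min/max over each
#' transcript's exons. Requires the rtracklayer package.
#'
#' @param path GTF file path.
#' @return a [transcript_structures()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gtf requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(df)) stop("no exon features in ", path)
  ex <- data.frame(
    transcript_id = as.character(df$transcript_id),
    gene_id = as.character(df$gene_id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = df$start,
    end = df$end,
    stringsAsFactors = FALSE
  )
  sp <- split(ex, ex$transcript_id)
  tr <- do.call(rbind, lapply(sp, function(d) data.frame(
    transcript_id = d$transcript_id[1L], gene_id = d$gene_id[1L],
    chrom = d$chrom[1L], strand = d$strand[1L],
    start = min(d$start), end = max(d$end), stringsAsFactors = FALSE)))
  rownames(tr) <- NULL
  transcript_structures(tr, ex[, c("transcript_id", "start", "end")])
}

#' Write transcript structures as GTF
#' @param structures a `TranscriptStructures` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(structures, path) {
  stopifnot(inherits(structures, "TranscriptStructures"))
  tr <- structures$transcripts
  ex <- merge(structures$exons, tr[, c("transcript_id", "gene_id", "chrom", "strand")],
              by = "transcript_id", sort = FALSE)
  ex <- ex[order(ex$transcript_id, ex$start), ]
  attr9 <- sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id)
  lines <- paste(ex$chrom, "isopair", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attr9, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

MUTATION_CLASSES <- c("nonsense", "missense", "frameshift", "indel",
                      "synonymous", "splice-site", "RNA")
PROTEIN_AFFECTING <- c("nonsense", "missense", "frameshift", "indel",
                       "splice-site")

#' Read a somatic mutation table
#'
#' Minimal MAF-derived TSV dialect: header columns `sample`, `chrom`,
#' `start`, `end`, `class` and optionally `gene`. Coordinates are 1-based
#' closed intervals.
#'
#' @param path file path.
#' @return data.frame of class `"MutationTable"`.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("mutations file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample", "chrom", "start", "end", "class")
  if (!all(need %in% names(dt)))
    stop("mutations file needs columns: ", paste(need, collapse = ", "))
  bad <- which(dt$start > dt$end)
  if (length(bad)) stop("mutation start > end at line ", bad[1L] + 1L)
  bad <- which(!dt$class %in% MUTATION_CLASSES)
  if (length(bad))
    stop("unknown mutation class '", dt$class[bad[1L]], "' at line ", bad[1L] + 1L)
  if (!"gene" %in% names(dt)) dt$gene <- NA_character_
  mutation_table(dt[, c("sample", "chrom", "start", "end", "class", "gene")])
}

#' Construct a mutation table
#' @param records data.frame with columns `sample`, `chrom`, `start`,
#'   `end`, `class` (one of nonsense, missense, frameshift, indel,
#'   synonymous, splice-site, RNA) and optionally `gene`.
#' @return the validated data.frame with class `"MutationTable"`.
#' @export
mutation_table <- function(records) {
  records <- as.data.frame(records)
  if (!"gene" %in% names(records)) records$gene <- NA_character_
  stopifnot(all(c("sample", "chrom", "start", "end", "class") %in% names(records)))
  if (any(records$start > records$end)) stop("mutation start > end")
  if (any(!records$class %in% MUTATION_CLASSES))
    stop("unknown mutation class: ",
         records$class[!records$class %in% MUTATION_CLASSES][1L])
  class(records) <- c("MutationTable", "data.frame")
  records
}

#' Export isoform pairs as GFF
#'
#' Writes one `transcript` feature plus its `exon` features per isoform of
#' each pair, tagging each line with the pair's gene and role
#' (tumor/normal isoform).
#'
#' @param pairs data.frame with columns `gene`, `tumor_isoform`,
#'   `normal_isoform` (e.g. a ranking or switch table).
#' @param structures a `TranscriptStructures` object covering the isoforms.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs_gff <- function(pairs, structures, path) {
  stopifnot(inherits(structures, "TranscriptStructures"))
  tr <- structures$transcripts
  ex <- structures$exons
  out <- character(0)
  for (r in seq_len(nrow(pairs))) {
    for (role in c("tumor_isoform", "normal_isoform")) {
      tid <- pairs[[role]][r]
      t1 <- tr[tr$transcript_id == tid, ]
      if (!nrow(t1)) stop("no structure for transcript ", tid)
      attr9 <- sprintf("ID=%s;gene=%s;role=%s", tid, pairs$gene[r],
                       sub("_isoform$", "", role))
      out <- c(out, paste(t1$chrom, "isopair", "transcript", t1$start, t1$end,
                          ".", t1$strand, ".", attr9, sep = "\t"))
      e1 <- ex[ex$transcript_id == tid, , drop = FALSE]
      e1 <- e1[order(e1$start), , drop = FALSE]
      out <- c(out, paste(t1$chrom, "isopair", "exon", e1$start, e1$end, ".",
                          t1$strand, ".", sprintf("Parent=%s", tid), sep = "\t"))
    }
  }
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}

#' Write a TSV with C-locale number formatting
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
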