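#' Map an annotation biotype onto a probe class
#'
#' Any biotype containing "pseudogene" maps to `pseudogene`;
#' `protein_coding` maps to `protein_coding`; everything else is treated as
#' lncRNA-like.
#'
#' @param biotype Character vector of biotypes.
#' @return Character vector of classes.
#' @export
biotype_class <- function(biotype) {
  ifelse(biotype == "protein_coding", "protein_coding",
         ifelse(grepl("pseudogene", biotype), "pseudogene", "lncRNA"))
}

validate_alignments <- function(alignments) {
  need <- c("probe_id", "chrom", "start", "end", "strand", "mismatches")
  stopifnot(is.data.frame(alignments), all(need %in% names(alignments)))
  bad <- alignments$start >= alignments$end
  if (any(bad)) {
    stop("malformed interval (start >= end) for probe: ",
         alignments$probe_id[which(bad)[1]])
  }
  if (any(alignments$mismatches < 0)) stop("mismatches must be >= 0")
  key <- paste(alignments$probe_id, alignments$chrom, alignments$start,
               alignments$end, alignments$strand)
  if (anyDuplicated(key)) {
    stop("duplicate alignment record for probe: ",
         alignments$probe_id[which(duplicated(key))[1]])
  }
  if (is.null(alignments$blocks)) {
    alignments$blocks <- sprintf("%d-%d", alignments$start, alignments$end)
  }
  alignments
}

#' Filter probe alignments by mismatches and number of loci
#'
#' Drops alignments with more than `max_mismatches` mismatches; probes whose
#' surviving alignments map to more than `max_loci` genomic loci are marked
#' excluded and contribute no approved alignments.
#'
#' @param alignments Data frame of probe alignments (columns `probe_id`,
#'   `chrom`, `start`, `end` in 0-based half-open coordinates, `strand`,
#'   `mismatches`, optional `blocks` as `"start-end,start-end"` sub-intervals
#'   of spliced alignments).
#' @param max_loci Maximum surviving loci per probe (default 4).
#' @param max_mismatches Maximum mismatches per alignment (default 2).
#' @return List with `approved` (data frame of surviving alignments) and
#'   `excluded` (character vector of probe ids excluded for multi-mapping).
#' @export
filter_alignments <- function(alignments, max_loci = 4, max_mismatches = 2) {
  alignments <- validate_alignments(alignments)
  keep <- alignments[alignments$mismatches <= max_mismatches, , drop = FALSE]
  n_loci <- table(keep$probe_id)
  excluded <- names(n_loci)[n_loci > max_loci]
  approved <- keep[!(keep$probe_id %in% excluded), , drop = FALSE]
  rownames(approved) <- NULL
  list(approved = approved, excluded = excluded)
}

#' Resolve competing annotation sources for one probe
#'
#' Picks the record from the highest-priority database
#' (GENCODE > Broad > LNCipedia > NONCODE); ties within a database are
#' broken by larger probe-exon overlap, then lexicographic gene id.
#'
#' @param records Data frame of candidate annotation records with columns
#'   `gene_id` and `source_db`.
#' @param overlap Optional numeric vector of probe-exon overlap widths, one
#'   per record (defaults to zero).
#' @return The single winning record (one-row data frame).
#' @export
resolve_annotation_source <- function(records, overlap = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no annotation records to resolve")
  }
  stopifnot(all(records$source_db %in% SOURCE_DBS))
  if (is.null(overlap)) overlap <- rep(0, nrow(records))
  pri <- match(records$source_db, SOURCE_DBS)
  ord <- order(pri, -overlap, records$gene_id)
  records[ord[1], , drop = FALSE]
}

blocks_to_ranges <- function(alignments) {
  # expand spliced alignments into one row per block
  parts <- strsplit(alignments$blocks, ",", fixed = TRUE)
  n_blk <- lengths(parts)
  idx <- rep(seq_len(nrow(alignments)), n_blk)
  se <- do.call(rbind, lapply(unlist(parts), function(b)
    as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])))
  GenomicRanges::GRanges(
    seqnames = alignments$chrom[idx],
    ranges = IRanges::IRanges(start = se[, 1] + 1, end = se[, 2]),
    strand = alignments$strand[idx],
    probe_id = alignments$probe_id[idx],
    row = idx)
}

annotation_granges <- function(annotations, feature = "exon") {
  if (feature == "exon") {
    GenomicRanges::GRanges(
      seqnames = annotations$chrom,
      ranges = IRanges::IRanges(start = annotations$exon_start + 1,
                                end = annotations$exon_end),
      strand = annotations$strand,
      gene_id = annotations$gene_id,
      row = seq_len(nrow(annotations)))
  } else {
    GenomicRanges::GRanges(
      seqnames = annotations$chrom,
      ranges = IRanges::IRanges(start = annotations$gene_start + 1,
                                end = annotations$gene_end),
      strand = annotations$strand,
      gene_id = annotations$gene_id,
      row = seq_len(nrow(annotations)))
  }
}

#' Classify one probe from its approved alignments
#'
#' Applies the hierarchical rules on same-strand, block-level exon overlap:
#' (1) any overlap with a protein-coding exon makes the probe
#' `protein_coding`; (2) otherwise a pseudogene exon overlap makes it
#' `pseudogene`; (3) otherwise a lncRNA exon overlap makes it `lncRNA`;
#' (4) probes overlapping only introns, only the opposite strand of a known
#' gene, or nothing at all are `poorly_annotated`. A probe aligning to
#' several loci inherits the highest-priority class across loci.
#'
#' @param approved Approved alignments of a single probe (data frame as in
#'   [filter_alignments()]).
#' @param annotations Annotation table (one row per exon: `gene_id`,
#'   `gene_name`, `source_db`, `biotype`, `chrom`, `strand`, `exon_start`,
#'   `exon_end`, `gene_start`, `gene_end`; 0-based half-open).
#' @param min_overlap Minimum overlap in bp between an alignment block and
#'   an exon (default 1).
#' @return List with `class` and `record` (winning one-row annotation record
#'   or NULL for poorly annotated probes).
#' @export
classify_probe <- function(approved, annotations, min_overlap = 1) {
  stopifnot(nrow(approved) >= 1)
  approved <- validate_alignments(approved)
  blocks <- blocks_to_ranges(approved)
  exons <- annotation_granges(annotations, "exon")
  hits <- GenomicRanges::findOverlaps(blocks, exons,
                                      minoverlap = min_overlap,
                                      ignore.strand = FALSE)
  if (length(hits) == 0) {
    return(list(class = "poorly_annotated", record = NULL))
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(blocks)[qh], IRanges::ranges(exons)[sh]))
  cand <- annotations[sh, , drop = FALSE]
  cand_class <- biotype_class(cand$biotype)
  for (cls in c("protein_coding", "pseudogene", "lncRNA")) {
    if (any(cand_class == cls)) {
      sel <- cand_class == cls
      agg <- tapply(ov[sel], cand$gene_id[sel], sum)
      recs <- cand[sel, , drop = FALSE]
      recs <- recs[!duplicated(recs$gene_id), , drop = FALSE]
      win <- resolve_annotation_source(recs,
                                       as.numeric(agg[recs$gene_id]))
      return(list(class = cls, record = win))
    }
  }
  list(class = "poorly_annotated", record = NULL)
}

#' Reannotate a probe platform
#'
#' Runs [filter_alignments()] and [classify_probe()] over every probe and
#' returns a platform-style annotation table plus per-class summary counts.
#'
#' @inheritParams filter_alignments
#' @inheritParams classify_probe
#' @return List with `table` (one row per probe: `probe_id`, `class`,
#'   `gene_id`, `gene_name`, `source_db`) and `summary` (named counts per
#'   class, including `excluded`, plus `total` and `approved`).
#' @export
annotate_platform <- function(alignments, annotations, max_loci = 4,
                              max_mismatches = 2, min_overlap = 1) {
  alignments <- validate_alignments(alignments)
  probe_ids <- unique(alignments$probe_id)
  flt <- filter_alignments(alignments, max_loci, max_mismatches)
  n_probes <- length(probe_ids)
  res <- data.frame(probe_id = probe_ids,
                    class = rep("excluded", n_probes),
                    gene_id = rep(NA_character_, n_probes),
                    gene_name = rep(NA_character_, n_probes),
                    source_db = rep(NA_character_, n_probes),
                    stringsAsFactors = FALSE)
  ok_ids <- setdiff(unique(flt$approved$probe_id), flt$excluded)
  for (pid in ok_ids) {
    cls <- classify_probe(
      flt$approved[flt$approved$probe_id == pid, , drop = FALSE],
      annotations, min_overlap)
    i <- match(pid, res$probe_id)
    res$class[i] <- cls$class
    if (!is.null(cls$record)) {
      res$gene_id[i] <- cls$record$gene_id
      res$gene_name[i] <- cls$record$gene_name
      res$source_db[i] <- cls$record$source_db
    }
  }
  counts <- setNames(integer(length(PROBE_CLASSES)), PROBE_CLASSES)
  tab <- table(res$class)
  counts[names(tab)] <- as.integer(tab)
  summary <- c(total = length(probe_ids),
               approved = sum(res$class != "excluded"), counts)
  list(table = res, summary = summary)
}

#' Read probe alignments from BED12 or PSL
#'
#' The format is auto-detected by column count (12 = BED12, 21 = PSL). For
#' BED12 the score column carries the mismatch count. Both are converted to
#' the internal 0-based half-open alignment table with spliced blocks.
#'
#' @param path Path to the alignment file.
#' @return Alignment data frame as consumed by [filter_alignments()].
#' @export
read_probe_alignments <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(first) == 12) {
    bed <- rtracklayer::import(path, format = "bed")
    blocks <- lapply(seq_along(bed), function(i) {
      bl <- bed$blocks[[i]]
      gstart <- GenomicRanges::start(bed)[i] - 1
      paste(sprintf("%d-%d", gstart + IRanges::start(bl) - 1,
                    gstart + IRanges::end(bl)), collapse = ",")
    })
    data.frame(probe_id = bed$name,
               chrom = as.character(GenomicRanges::seqnames(bed)),
               start = GenomicRanges::start(bed) - 1,
               end = GenomicRanges::end(bed),
               strand = as.character(GenomicRanges::strand(bed)),
               mismatches = as.integer(bed$score),
               blocks = unlist(blocks),
               stringsAsFactors = FALSE)
  } else if (length(first) == 21) {
    psl <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(psl) <- c("matches", "mismatches", "rep_matches", "n_count",
                    "q_num_insert", "q_base_insert", "t_num_insert",
                    "t_base_insert", "strand", "q_name", "q_size",
                    "q_start", "q_end", "t_name", "t_size", "t_start",
                    "t_end", "block_count", "block_sizes", "q_starts",
                    "t_starts")
    blocks <- vapply(seq_len(nrow(psl)), function(i) {
      sizes <- as.numeric(strsplit(psl$block_sizes[i], ",")[[1]])
      starts <- as.numeric(strsplit(psl$t_starts[i], ",")[[1]])
      paste(sprintf("%d-%d", starts, starts + sizes), collapse = ",")
    }, "")
    data.frame(probe_id = psl$q_name, chrom = psl$t_name,
               start = psl$t_start, end = psl$t_end,
               strand = substr(psl$strand, nchar(psl$strand), nchar(psl$strand)),
               mismatches = psl$mismatches, blocks = blocks,
               stringsAsFactors = FALSE)
  } else {
    stop("unrecognised alignment format (expected 12 BED or 21 PSL columns)")
  }
}

#' Read a gene annotation from GTF
#'
#' Imports exon features; the GTF `source` column is taken as the annotation
#' database (GENCODE, Broad, LNCipedia, NONCODE) and the `gene_biotype`
#' attribute as the biotype. Coordinates are converted from 1-based
#' inclusive to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return Annotation data frame (one row per exon) as consumed by
#'   [classify_probe()].
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  gene <- gr[gr$type == "gene"]
  gidx <- match(ex$gene_id, gene$gene_id)
  data.frame(
    gene_id = ex$gene_id,
    gene_name = if (!is.null(ex$gene_name)) ex$gene_name else ex$gene_id,
    source_db = as.character(ex$source),
    biotype = ex$gene_biotype,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    exon_start = GenomicRanges::start(ex) - 1,
    exon_end = GenomicRanges::end(ex),
    gene_start = GenomicRanges::start(gene)[gidx] - 1,
    gene_end = GenomicRanges::end(gene)[gidx],
    stringsAsFactors = FALSE)
}

#' Write a platform annotation table and its class summary
#'
#' @param annotation Result of [annotate_platform()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_probe_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(annotation$table, file.path(dir, "probe_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(class = names(annotation$summary),
                         n = as.integer(annotation$summary)),
              file.path(dir, "probe_class_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
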