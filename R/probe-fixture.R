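# Synthetic probe-annotation fixture: a miniature genome exercising every
# classification outcome of the reannotation rules.

#' Generate a probe-annotation fixture with known expected classes
#'
#' Builds a small synthetic annotation catalog (protein-coding gene with
#' introns, pseudogene, lncRNAs duplicated across databases, an
#' opposite-strand gene and empty regions) plus probes covering every
#' classification outcome: protein-coding, pseudogene, lncRNA, poorly
#' annotated (intron-only, opposite strand, unannotated), excluded by
#' multi-mapping (5 loci) and excluded by mismatches. The seed jitters probe
#' offsets inside their target exons; the expected class of every probe is
#' recorded.
#'
#' @param seed Integer seed.
#' @return List with `alignments` (probe alignment table), `annotations`
#'   (exon-level annotation table) and `expected` (data frame `probe_id`,
#'   `class`, `gene_id`).
#' @export
generate_probe_fixture <- function(seed = 1) {
  set.seed(seed)
  probe_len <- 60
  ann <- function(gene_id, gene_name, db, biotype, chrom, strand, exons,
                  gene_start, gene_end) {
    data.frame(gene_id = gene_id, gene_name = gene_name, source_db = db,
               biotype = biotype, chrom = chrom, strand = strand,
               exon_start = vapply(exons, `[`, 0, 1),
               exon_end = vapply(exons, `[`, 0, 2),
               gene_start = gene_start, gene_end = gene_end,
               stringsAsFactors = FALSE)
  }
  annotations <- rbind(
    ann("PCA", "PCA", "GENCODE", "protein_coding", "chr1", "+",
        list(c(1000, 1500), c(3000, 3500), c(4500, 5000)), 1000, 5000),
    ann("PSG1", "PSG1", "GENCODE", "processed_pseudogene", "chr1", "+",
        list(c(8000, 9000)), 8000, 9000),
    ann("LNC1", "LNC1", "GENCODE", "lincRNA", "chr1", "+",
        list(c(12000, 13000)), 12000, 13000),
    ann("NONC1", "NONC1", "NONCODE", "lncRNA", "chr1", "+",
        list(c(12000, 13200)), 12000, 13200),
    ann("LNCP1", "LNCP1", "LNCipedia", "lncRNA", "chr1", "+",
        list(c(16000, 17000)), 16000, 17000),
    ann("BRD1", "BRD1", "Broad", "lincRNA", "chr1", "+",
        list(c(16000, 17050)), 16000, 17050),
    ann("PCB", "PCB", "GENCODE", "protein_coding", "chr1", "-",
        list(c(20000, 21000)), 20000, 21000),
    # lncRNA exon overlapping a protein-coding exon: rule 1 must win there
    ann("NONC2", "NONC2", "NONCODE", "lncRNA", "chr1", "+",
        list(c(3200, 4000)), 3200, 4000))

  jit <- function(lo, hi) lo + sample.int(hi - lo - probe_len, 1)
  aln <- function(probe_id, start, chrom = "chr1", strand = "+",
                  mismatches = 0, blocks = NULL) {
    end <- start + probe_len
    data.frame(probe_id = probe_id, chrom = chrom, start = start, end = end,
               strand = strand, mismatches = mismatches,
               blocks = if (is.null(blocks))
                 sprintf("%d-%d", start, end) else blocks,
               stringsAsFactors = FALSE)
  }
  # spliced probe: first block ends at the PCA exon1/intron boundary
  # (1500), second block resumes in exon2; block lengths sum to probe_len
  spliced_start <- 1441 + sample.int(57, 1)
  spliced_b1_end <- 1500
  spliced_b2_len <- probe_len - (spliced_b1_end - spliced_start)
  alignments <- rbind(
    aln("p_pc", jit(1000, 1500)),
    # spans the PCA exon2/pseudogene boundary region: one locus in PCA exon,
    # a second locus in the pseudogene exon -> rule 1 wins
    aln("p_pc_pg", jit(3000, 3500)),
    aln("p_pc_pg", jit(8000, 9000)),
    aln("p_pg", jit(8000, 9000)),
    aln("p_pc_lnc", jit(3200, 3500)),
    aln("p_lnc", jit(12000, 13000)),
    aln("p_lnc_db", jit(16000, 17000)),
    aln("p_intron", jit(1600, 2900)),
    aln("p_anti", jit(20000, 21000), strand = "+"),
    aln("p_none", jit(30000, 40000)),
    do.call(rbind, lapply(0:4, function(i)
      aln("p_multi", 50000 + i * 10000))),
    aln("p_mm", jit(12000, 13000), mismatches = 3),
    do.call(rbind, lapply(0:3, function(i)
      aln("p_four", 90000 + i * 10000))),
    aln("p_four_lnc", jit(12000, 13000)),
    aln("p_spliced", spliced_start,
        blocks = sprintf("%d-%d,%d-%d", spliced_start, spliced_b1_end,
                         3000, 3000 + spliced_b2_len)))
  alignments[alignments$probe_id == "p_spliced", c("start", "end")] <-
    c(spliced_start, 3000 + spliced_b2_len)
  expected <- data.frame(
    probe_id = c("p_pc", "p_pc_pg", "p_pc_lnc", "p_lnc", "p_lnc_db", "p_pg",
                 "p_intron", "p_anti", "p_none", "p_multi", "p_mm",
                 "p_four", "p_four_lnc", "p_spliced"),
    class = c("protein_coding", "protein_coding", "protein_coding",
              "lncRNA", "lncRNA", "pseudogene", "poorly_annotated",
              "poorly_annotated", "poorly_annotated", "excluded",
              "excluded", "poorly_annotated", "lncRNA", "protein_coding"),
    gene_id = c("PCA", "PCA", "PCA", "LNC1", "BRD1", "PSG1", NA, NA, NA,
                NA, NA, NA, "LNC1", "PCA"),
    stringsAsFactors = FALSE)
  list(alignments = alignments, annotations = annotations,
       expected = expected)
}

#' Write a probe fixture as BED12 + GTF
#'
#' Alignments go to `alignments.bed` (BED12; the score column carries the
#' mismatch count), annotations to `annotation.gtf` (1-based inclusive; the
#' GTF source column carries the database, `gene_biotype` the biotype).
#'
#' @param fixture Result of [generate_probe_fixture()] (or any list with
#'   `alignments` and `annotations` tables).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_probe_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  al <- fixture$alignments
  int <- function(x) formatC(x, format = "d")
  bed <- vapply(seq_len(nrow(al)), function(i) {
    parts <- strsplit(al$blocks[i], ",", fixed = TRUE)[[1]]
    se <- vapply(parts, function(b)
      as.numeric(strsplit(b, "-", fixed = TRUE)[[1]]), numeric(2))
    sizes <- se[2, ] - se[1, ]
    rel <- se[1, ] - al$start[i]
    paste(al$chrom[i], int(al$start[i]), int(al$end[i]), al$probe_id[i],
          al$mismatches[i], al$strand[i], int(al$start[i]),
          int(al$end[i]), "0", length(parts),
          paste0(paste(int(sizes), collapse = ","), ","),
          paste0(paste(int(rel), collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(bed, file.path(dir, "alignments.bed"))

  an <- fixture$annotations
  gene_rows <- an[!duplicated(an$gene_id), , drop = FALSE]
  gtf_line <- function(chrom, db, feat, start0, end0, strand, gene_id,
                       gene_name, biotype) {
    sprintf(paste0("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                   "gene_name \"%s\"; gene_biotype \"%s\";"),
            chrom, db, feat, as.integer(start0 + 1), as.integer(end0),
            strand, gene_id, gene_name, biotype)
  }
  lines <- c(
    vapply(seq_len(nrow(gene_rows)), function(i)
      gtf_line(gene_rows$chrom[i], gene_rows$source_db[i], "gene",
               gene_rows$gene_start[i], gene_rows$gene_end[i],
               gene_rows$strand[i], gene_rows$gene_id[i],
               gene_rows$gene_name[i], gene_rows$biotype[i]), ""),
    vapply(seq_len(nrow(an)), function(i)
      gtf_line(an$chrom[i], an$source_db[i], "exon", an$exon_start[i],
               an$exon_end[i], an$strand[i], an$gene_id[i],
               an$gene_name[i], an$biotype[i]), ""))
  writeLines(lines, file.path(dir, "annotation.gtf"))
  invisible(dir)
}
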