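test_that("alignment filtering enforces mismatch and locus limits", {
  aln <- function(id, start, mm = 0) {
    data.frame(probe_id = id, chrom = "chr1", start = start,
               end = start + 60, strand = "+", mismatches = mm,
               stringsAsFactors = FALSE)
  }
  five <- do.call(rbind, lapply(0:4, function(i) aln("p5", i * 1000)))
  res <- filter_alignments(five)
  expect_equal(res$excluded, "p5")
  expect_equal(nrow(res$approved), 0)

  res <- filter_alignments(aln("pm", 0, mm = 3))
  expect_equal(nrow(res$approved), 0)
  expect_length(res$excluded, 0)  # dropped by mismatches, not multi-mapping

  four <- do.call(rbind, lapply(0:3, function(i) aln("p4", i * 1000, mm = 2)))
  res <- filter_alignments(four)
  expect_equal(nrow(res$approved), 4)

  bad <- aln("pb", 100); bad$end <- 50
  expect_error(filter_alignments(bad), "pb")
})

test_that("annotation sources resolve by database priority", {
  rec <- function(id, db) data.frame(gene_id = id, source_db = db,
                                     stringsAsFactors = FALSE)
  expect_equal(resolve_annotation_source(
    rbind(rec("n1", "NONCODE"), rec("g1", "GENCODE")))$gene_id, "g1")
  expect_equal(resolve_annotation_source(
    rbind(rec("l1", "LNCipedia"), rec("b1", "Broad")))$gene_id, "b1")
  expect_equal(resolve_annotation_source(rec("x", "NONCODE"))$gene_id, "x")
  # ties within a source: larger overlap, then lexicographic gene id
  two <- rbind(rec("zz", "GENCODE"), rec("aa", "GENCODE"))
  expect_equal(resolve_annotation_source(two, overlap = c(50, 10))$gene_id,
               "zz")
  expect_equal(resolve_annotation_source(two)$gene_id, "aa")
  expect_error(resolve_annotation_source(rec("x", "NONCODE")[0, ]), "resolve")
})

test_that("the classification hierarchy matches the four rules exactly", {
  combos <- expand.grid(pc = c(TRUE, FALSE), pg = c(TRUE, FALSE),
                        lnc = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    present <- c("pc", "pg", "lnc")[unlist(combos[i, ])]
    ann <- truth_table_annotations(present)
    got <- classify_probe(truth_table_probe(), ann)$class
    want <- if (combos$pc[i]) "protein_coding"
    else if (combos$pg[i]) "pseudogene"
    else if (combos$lnc[i]) "lncRNA"
    else "poorly_annotated"
    expect_equal(got, want,
                 info = paste("combo:", paste(present, collapse = "+")))
  }
})

test_that("opposite-strand and intron-only evidence fall to rule 4", {
  # protein-coding exon on the minus strand under a plus-strand probe
  ann <- truth_table_annotations("pc", strand = "-")
  expect_equal(classify_probe(truth_table_probe(), ann)$class,
               "poorly_annotated")
  # probe inside an intron of an annotated gene
  intron_ann <- data.frame(
    gene_id = "G1", gene_name = "G1", source_db = "GENCODE",
    biotype = "protein_coding", chrom = "chr1", strand = "+",
    exon_start = c(0, 900), exon_end = c(50, 1000),
    gene_start = 0, gene_end = 1000, stringsAsFactors = FALSE)
  expect_equal(classify_probe(truth_table_probe(), intron_ann)$class,
               "poorly_annotated")
})

test_that("adding a protein-coding exon overlap always dominates", {
  for (present in list("pg", "lnc", c("pg", "lnc"), character(0))) {
    ann <- truth_table_annotations(c(present, "pc"))
    expect_equal(classify_probe(truth_table_probe(), ann)$class,
                 "protein_coding")
  }
})

test_that("the synthetic probe fixture is classified as recorded", {
  fix <- generate_probe_fixture(seed = 4)
  res <- annotate_platform(fix$alignments, fix$annotations)
  got <- res$table[match(fix$expected$probe_id, res$table$probe_id), ]
  expect_equal(got$class, fix$expected$class)
  ok <- !is.na(fix$expected$gene_id)
  expect_equal(got$gene_id[ok], fix$expected$gene_id[ok])
  # class counts partition the probe universe
  cls <- res$summary[c("protein_coding", "pseudogene", "lncRNA",
                       "poorly_annotated", "excluded")]
  expect_equal(sum(cls), unname(res$summary["total"]))
  expect_equal(unname(res$summary["approved"]),
               unname(res$summary["total"] - res$summary["excluded"]))
  expect_identical(generate_probe_fixture(seed = 4)$alignments,
                   fix$alignments)
})

test_that("fixtures survive a BED12 + GTF round trip", {
  fix <- generate_probe_fixture(seed = 9)
  dir <- withr::local_tempdir()
  write_probe_fixture(fix, dir)
  al <- read_probe_alignments(file.path(dir, "alignments.bed"))
  an <- read_gene_annotation(file.path(dir, "annotation.gtf"))
  res <- annotate_platform(al, an)
  got <- res$table[match(fix$expected$probe_id, res$table$probe_id), ]
  expect_equal(got$class, fix$expected$class)
})

test_that("degenerate platform inputs are handled", {
  fix <- generate_probe_fixture(seed = 1)
  empty <- fix$alignments[0, ]
  res <- annotate_platform(empty, fix$annotations)
  expect_equal(nrow(res$table), 0)
  expect_equal(unname(res$summary["total"]), 0L)
  # all probes excluded -> approved 0
  all_mm <- fix$alignments[fix$alignments$probe_id == "p_mm", ]
  res <- annotate_platform(all_mm, fix$annotations)
  expect_equal(unname(res$summary["approved"]), 0L)
  dup <- rbind(fix$alignments, fix$alignments[1, ])
  expect_error(annotate_platform(dup, fix$annotations), "duplicate")
})
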