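test_that("location categories follow the precedence rules", {
  ann <- toy_annotation()
  snps <- data.frame(
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrA", "chrA", "chrA",
              "chrA", "chrA"),
    pos = c(2300,   # inside CDS of txP
            1500,   # 500 bp upstream of txP start, outside all genes
            2601,   # first intron base after exon1 end -> splicing
            3000,   # deep intron of txP
            2100,   # 5' UTR exon part
            4500,   # 3' UTR exon part
            12100,  # ncRNA span
            5500,   # 500 bp downstream of txP end
            18000)) # far from everything
  got <- classify_location(snps, ann)
  expect_identical(got, c("coding", "updownstream", "splicing", "intronic",
                          "UTR5", "UTR3", "ncRNA", "updownstream",
                          "intergenic"))

  # intronic beats up/downstream of a neighbouring gene: a SNP in the
  # intron of txP that is also within 1 kb of another transcript
  ann2 <- toy_annotation()
  ann2$transcripts <- rbind(ann2$transcripts,
                            data.table::data.table(tx_id = "txQ",
                                                   gene_id = "geneQ",
                                                   chrom = "chrA",
                                                   strand = "+",
                                                   start = 3500L, end = 3600L,
                                                   coding = FALSE))
  ann2$exons <- rbind(ann2$exons,
                      data.table::data.table(tx_id = "txQ", start = 3500L,
                                             end = 3600L))
  # position 3000 is in txP's intron and 500 bp upstream of txQ; txQ is
  # noncoding so ncRNA would win only if the SNP were inside its span
  got2 <- classify_location(data.frame(chrom = "chrA", pos = 3000), ann2)
  expect_identical(got2, "intronic")

  expect_warning(
    off <- classify_location(data.frame(chrom = "chrZZ", pos = 5), ann),
    "unannotated")
  expect_identical(off, "intergenic")
})

test_that("splice-site calls are confined to 2 bp of intron boundaries", {
  ann <- toy_annotation()
  # intron of txP spans [2600, 4000): splicing bases are 0-based
  # 2600,2601 (donor side) and 3998,3999 (acceptor side)
  pos <- c(2601, 2602, 2603, 3999, 4000, 3998)
  got <- classify_location(data.frame(chrom = "chrA", pos = pos), ann)
  expect_identical(got, c("splicing", "splicing", "intronic",
                          "splicing", "splicing", "intronic"))
})

test_that("coding effects are strand-aware codon translations", {
  fx <- toy_coding_fixture()
  # + strand codons at 1-based 101..112: CGG GGA TGG TAG
  expect_identical(coding_effect("chrB", 101, "C", "T", fx$ann, fx$ref),
                   "nonsynonymous")   # CGG -> TGG, R -> W
  expect_identical(coding_effect("chrB", 106, "A", "G", fx$ann, fx$ref),
                   "synonymous")      # GGA -> GGG
  expect_identical(coding_effect("chrB", 108, "G", "A", fx$ann, fx$ref),
                   "stop-gain")       # TGG -> TAG
  expect_identical(coding_effect("chrB", 112, "G", "C", fx$ann, fx$ref),
                   "stop-loss")       # TAG -> TAC

  # - strand gene with coding sequence ATG CGG TGG TAA: the second codon's
  # first base sits at genomic position 209 on the plus strand as G; a
  # G>A genomic change is C>T on the coding strand, CGG -> TGG
  expect_identical(coding_effect("chrB", 209, "G", "A", fx$ann, fx$ref),
                   "nonsynonymous")
  # third codon TGG: genomic plus-strand bases 203..205 = CCA; changing
  # position 204 C>T makes coding TGG -> TAG? no: coding base is
  # complement(C)=G at coding position 7 (second base of TGG), G>A gives
  # stop codon TAG
  expect_identical(coding_effect("chrB", 204, "C", "T", fx$ann, fx$ref),
                   "stop-gain")

  # a transcript whose CDS length is not a multiple of 3 is skipped
  bad <- fx$ann
  bad$cds <- data.table::copy(bad$cds)
  bad$cds$end[bad$cds$tx_id == "txF"] <- 111L
  expect_warning(
    expect_warning(out <- coding_effect("chrB", 101, "C", "T",
                                        genome_annotation(bad$transcripts,
                                                          bad$exons, bad$cds),
                                        fx$ref),
                   "multiple of 3"),
    "no valid CDS")
  expect_true(is.na(out))
})

test_that("interval overlap reports both directional fractions", {
  dss <- data.frame(chrom = "chr1", start = 0, end = 60000)
  qtl <- data.frame(chrom = "chr1", start = c(50000, 200000),
                    end = c(70000, 300000), id = c("q1", "q2"))
  ov <- interval_overlap(dss, qtl)
  expect_equal(ov$frac_query, 1)
  expect_equal(ov$frac_features, 0.5)
  expect_identical(ov$hits$feature_id, "q1")

  # abutting half-open intervals do not overlap
  ab <- interval_overlap(dss, data.frame(chrom = "chr1", start = 60000,
                                         end = 70000))
  expect_equal(ab$frac_query, 0)

  # empty query
  e <- interval_overlap(dss[0, ], qtl)
  expect_equal(e$frac_query, 0)
  expect_identical(nrow(e$hits), 0L)

  # symmetry: swapping roles swaps the directional fractions
  sw <- interval_overlap(qtl, dss)
  expect_equal(sw$frac_query, ov$frac_features)
  expect_equal(sw$frac_features, ov$frac_query)
})

test_that("group-specific SNPs and their nearly fixed subset", {
  sites <- make_site_table("chr1", c(10L, 20L, 30L, 40L),
                           n_A = 10, p_A = c(0.95, 0.4, 0.3, 0),
                           h_A = 0, pi_A = 0.1,
                           n_B = 10, p_B = c(0, 0, 0.2, 0.5),
                           h_B = 0, pi_B = 0.1)
  gs <- group_specific_snps(sites, "A")
  expect_identical(gs$specific$pos, c(10L, 20L))
  expect_identical(gs$nearly_fixed$pos, 10L)
  # the threshold is strict
  sites2 <- make_site_table("chr1", 10L, 10, 0.9, 0, 0.1, 10, 0, 0, 0.1)
  expect_identical(nrow(group_specific_snps(sites2, "A")$nearly_fixed), 0L)
  # a group with no calls does not block specificity
  sites3 <- make_site_table("chr1", 10L, 10, 0.5, 0, 0.1,
                            0, NA_real_, NA_real_, NA_real_)
  expect_identical(nrow(group_specific_snps(sites3, "A")$specific), 1L)
  expect_error(group_specific_snps(sites, "Z"), "focal group")
})

test_that("category enrichment divides observed by genome fractions", {
  obs <- c(noncoding = 0.9820, coding = 0.0180)
  gen <- c(noncoding = 0.9692, coding = 0.0308)
  r <- category_enrichment(obs, gen)
  expect_equal(r[["noncoding"]], 1.0132, tolerance = 1e-4)
  expect_equal(r[["coding"]], 0.584, tolerance = 1e-3)
  expect_equal(unname(category_enrichment(gen, gen)), c(1, 1))
  expect_warning(z <- category_enrichment(c(x = 0.1), c(x = 0)), "zero")
  expect_true(is.na(z[["x"]]))
})

test_that("GFF3 gene models round-trip through rtracklayer", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\ttest\tgene\t2001\t5000\t.\t+\t.\tID=geneP",
    "chrA\ttest\tmRNA\t2001\t5000\t.\t+\t.\tID=txP;Parent=geneP",
    "chrA\ttest\texon\t2001\t2600\t.\t+\t.\tID=e1;Parent=txP",
    "chrA\ttest\texon\t4001\t5000\t.\t+\t.\tID=e2;Parent=txP",
    "chrA\ttest\tCDS\t2201\t2600\t.\t+\t0\tID=c1;Parent=txP",
    "chrA\ttest\tCDS\t4001\t4400\t.\t+\t0\tID=c2;Parent=txP",
    "chrA\ttest\tncRNA\t12001\t12500\t.\t+\t.\tID=txN;Parent=ncR"),
    gff)
  ann <- read_annotation(gff)
  expect_identical(sort(ann$transcripts$tx_id), c("txN", "txP"))
  expect_identical(ann$transcripts$start[ann$transcripts$tx_id == "txP"],
                   2000L)
  expect_identical(ann$transcripts$coding,
                   ann$transcripts$tx_id == "txP")
  got <- classify_location(
    data.frame(chrom = "chrA", pos = c(2300, 3000, 12100, 18000)), ann)
  expect_identical(got, c("coding", "intronic", "ncRNA", "intergenic"))
})
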