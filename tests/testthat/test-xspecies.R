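mk_profile <- function(ids, lfc_ch, q_ch, lfc_hf, q_hf) {
  data.frame(gene_id = ids, log2fc_ch = lfc_ch, q_ch = q_ch,
             log2fc_hf = lfc_hf, q_hf = q_hf,
             direction_ch = classify_direction(lfc_ch, q_ch),
             direction_hf = classify_direction(lfc_hf, q_hf))
}

test_that("ortholog join keeps only 1:1 pairs present in both tables", {
  h <- mk_profile(c("H1", "H2", "H3"), c(2, 2, 2), 0.01, c(3, 3, 3), 0.01)
  m <- mk_profile(c("M1", "M2", "M4"), c(2, 2, 2), 0.01, c(3, 3, 3), 0.01)
  map <- data.frame(human_id = c("H1", "H2", "H3", "H3"),
                    mouse_id = c("M1", "M2", "M3", "M4"),
                    mapping_type = "one2one")
  j <- join_orthologs(h, m, map)
  expect_equal(j$human_id, c("H1", "H2"))    # H3 is 1:many, dropped
  expect_equal(attr(j, "n_dropped_non11"), 2L)
  # disjoint gene sets: error
  map2 <- data.frame(human_id = "HX", mouse_id = "MX",
                     mapping_type = "one2one")
  expect_error(join_orthologs(h, m, map2), "no ortholog pair")
  # single shared pair
  j2 <- join_orthologs(h, m, map[1, ])
  expect_equal(nrow(j2), 1)
  # explicit non-1:1 mapping type excluded
  map3 <- map[1:2, ]; map3$mapping_type[2] <- "one2many"
  expect_equal(nrow(join_orthologs(h, m, map3)), 1)
})

test_that("profile classification enumerates the stage-call rules", {
  expect_equal(unname(classify_profile(list(log2fc_ch = 1.6, q_ch = 0.01,
                                            log2fc_hf = 2.6, q_hf = 0.001))),
               c("up", "up"))
  expect_equal(unname(classify_profile(list(log2fc_ch = 0.2, q_ch = 0.01,
                                            log2fc_hf = -0.1, q_hf = 0.01))),
               c("ns", "ns"))
  expect_equal(unname(classify_profile(list(log2fc_ch = 1.5, q_ch = 0.2,
                                            log2fc_hf = 1.5, q_hf = 0.01))),
               c("ns", "up"))
  expect_equal(unname(classify_profile(list(log2fc_ch = -1.2, q_ch = 0.01,
                                            log2fc_hf = -3, q_hf = 0.2))),
               c("down", "ns"))
  expect_error(classify_profile(list(log2fc_ch = 1)), "both contrasts")
  # threshold is strict: |lfc| exactly at the cut is not called
  expect_equal(unname(classify_profile(list(log2fc_ch = 1, q_ch = 1e-5,
                                            log2fc_hf = 2, q_hf = 1e-5)))[1],
               "ns")
})

test_that("conserved set keeps identical non-null patterns only", {
  h <- mk_profile(paste0("H", 1:3),
                  c(2, 2, 0.1), c(0.01, 0.01, 0.5),
                  c(3, 3, 0.1), c(0.01, 0.01, 0.5))
  m <- mk_profile(paste0("M", 1:3),
                  c(2, -2, 0.1), c(0.01, 0.01, 0.5),
                  c(3, -3, 0.1), c(0.01, 0.01, 0.5))
  map <- data.frame(human_id = paste0("H", 1:3), mouse_id = paste0("M", 1:3),
                    mapping_type = "one2one")
  cs <- conserved_set(join_orthologs(h, m, map))
  # H1 concordant up-up, H2 sign-discordant, H3 (ns, ns): only H1 survives
  expect_equal(cs$entries$human_gene, "H1")
  expect_equal(cs$entries$class, "up-up")
  expect_equal(dim(cs$heatmap), c(1L, 4L))
  expect_equal(unname(cs$heatmap[1, ]), c(2, 3, 2, 3))
})

test_that("species symmetry: swapping the tables preserves the pair set", {
  tabs <- gen_de_tables(concordance_preset(n_genes = 500, n_planted = 8),
                        seed = 3)
  ph <- species_profiles(tabs$human$ch, tabs$human$hf)
  pm <- species_profiles(tabs$mouse$ch, tabs$mouse$hf)
  map <- tabs$ortholog_map
  cs1 <- conserved_set(join_orthologs(ph, pm, map))
  map_sw <- data.frame(human_id = map$mouse_id, mouse_id = map$human_id,
                       mapping_type = map$mapping_type)
  cs2 <- conserved_set(join_orthologs(pm, ph, map_sw))
  expect_setequal(paste(cs1$entries$human_gene, cs1$entries$mouse_gene),
                  paste(cs2$entries$mouse_gene, cs2$entries$human_gene))
})

test_that("planted concordant genes are recovered on a null background", {
  pre <- concordance_preset(n_genes = 3000, n_planted = 12)
  tabs <- gen_de_tables(pre, seed = 5)
  ph <- species_profiles(tabs$human$ch, tabs$human$hf)
  pm <- species_profiles(tabs$mouse$ch, tabs$mouse$hf)
  cs <- conserved_set(join_orthologs(ph, pm, tabs$ortholog_map))
  planted <- sprintf("HGENE%05d", 1:12)
  expect_gte(mean(planted %in% cs$entries$human_gene), 0.9)
  # the CRISPLD1-like gene carries its printed per-stage effects
  tr <- tabs$counts$human$truth$log2fc
  expect_equal(unname(tr["HGENE00001", c("CH", "mHF")]), c(1.6, 2.6))
  trm <- tabs$counts$mouse$truth$log2fc
  expect_equal(unname(trm["MGENE00001", c("w1TAC", "w8TAC")]), c(1.5, 2.3))
  # ortholog map is a bijection
  expect_false(anyDuplicated(pre$ortholog_map$human_id) > 0)
  expect_false(anyDuplicated(pre$ortholog_map$mouse_id) > 0)
})

test_that("pure-null preset yields an (almost) empty conserved set", {
  pre <- concordance_preset(n_genes = 3000, n_planted = 0)
  tabs <- gen_de_tables(pre, seed = 6)
  ph <- species_profiles(tabs$human$ch, tabs$human$hf)
  pm <- species_profiles(tabs$mouse$ch, tabs$mouse$hf)
  cs <- conserved_set(join_orthologs(ph, pm, tabs$ortholog_map))
  expect_lte(nrow(cs$entries), 1)
})

test_that("heatmap export round-trips and rejects empty sets", {
  tabs <- gen_de_tables(concordance_preset(n_genes = 400, n_planted = 5),
                        seed = 2)
  ph <- species_profiles(tabs$human$ch, tabs$human$hf)
  pm <- species_profiles(tabs$mouse$ch, tabs$mouse$hf)
  cs <- conserved_set(join_orthologs(ph, pm, tabs$ortholog_map))
  tf <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(cs, tf)
  back <- utils::read.delim(tf, check.names = FALSE)
  expect_equal(nrow(back), nrow(cs$heatmap))
  expect_equal(as.matrix(back[, -1]), unname(cs$heatmap) * 1,
               ignore_attr = TRUE)
  empty <- structure(list(entries = data.frame(), heatmap = matrix(0, 0, 4)),
                     class = "conserved_gene_set")
  expect_error(export_heatmap_matrix(empty, tf), "empty")
})
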