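test_that("the amino-acid property table is total and matches the published codes", {
  expect_setequal(rownames(aa_property_table),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  # all 80 cells, column by column (volume, hydrophobicity, charge, polarity)
  expected <- list(
    A = c(1, 2, 0, 1), C = c(2, 2, 0, 1), D = c(2, 0, -1, 0),
    E = c(3, 0, -1, 0), F = c(5, 3, 0, 1), G = c(1, 1, 0, 1),
    H = c(3, 1, 1, 0), I = c(4, 3, 0, 1), K = c(4, 0, 1, 0),
    L = c(4, 3, 0, 1), M = c(4, 3, 0, 1), N = c(2, 0, 0, 0),
    P = c(2, 0, 0, 1), Q = c(3, 1, 0, 0), R = c(4, 0, 1, 0),
    S = c(1, 1, 0, 0), T = c(2, 1, 0, 0), V = c(3, 3, 0, 1),
    W = c(5, 3, 0, 0), Y = c(5, 2, 0, 0))
  for (aa in names(expected)) {
    expect_equal(unname(aa_properties(aa)), expected[[aa]],
                 info = paste("amino acid", aa))
  }
  expect_error(aa_properties("B"), "unknown amino acid")
  expect_error(aa_properties("a"), "unknown amino acid")
})

test_that("indel numeric summaries are sums and means of the codes", {
  expect_equal(indel_numeric("AG", "volume", "total"), 2)
  expect_equal(indel_numeric("AG", "volume", "average"), 1)
  expect_equal(indel_numeric("W", "hydrophobicity", "average"), 3)
  expect_equal(indel_numeric("DE", "charge", "total"), -2)
  expect_error(indel_numeric("AZ", "volume", "total"), "non-standard")
})

test_that("semantic mapping rounds half away from zero and rescales totals", {
  expect_identical(to_semantic(1, "volume", "average"), "very_small")
  expect_identical(to_semantic(3, "hydrophobicity", "average"),
                   "very_hydrophobic")
  expect_identical(to_semantic(0, "charge", "average"), "neutral")
  # a total lives on the per-residue scale after dividing by length
  expect_identical(to_semantic(10, "volume", "total", n_residues = 2),
                   "very_large")
  # 2.5 rounds away from zero to 3, not to even
  expect_identical(to_semantic(2.5, "volume", "average"), "medium")
  expect_identical(to_semantic(-0.5, "charge", "average"), "negative")
  # out-of-scale codes clamp with a warning
  expect_warning(lab <- to_semantic(9, "volume", "average"), "clamped")
  expect_identical(lab, "very_large")
})

test_that("local sequence scopes follow the site/environment/region bookkeeping", {
  ctx <- toy_context("MKVANQWLLA")
  del <- indel_variant("P1", 5, "deletion", "N")
  ls <- local_sequences(del, ctx)
  expect_identical(ls$site, "Q")
  expect_identical(ls$environment, "AQ")
  expect_identical(ls$region, "VAQW")
  expect_identical(ls$site_positions, 6L)

  ins <- indel_variant("P1", 3, "insertion", "GG")
  ls2 <- local_sequences(ins, toy_context("MKVAN"))
  expect_identical(ls2$site, "VA")
  expect_identical(ls2$environment, "MKVA")
  expect_identical(ls2$region, "MKVAN")

  # deletion of the last residue: site falls back upstream
  last <- indel_variant("P1", 5, "deletion", "N")
  ls3 <- local_sequences(last, toy_context("MKVAN"))
  expect_identical(ls3$site, "A")
  expect_identical(ls3$site_positions, 4L)

  # truncation at the N-terminus
  first <- indel_variant("P1", 1, "deletion", "M")
  ls4 <- local_sequences(first, toy_context("MKVAN"))
  expect_identical(ls4$site, "K")
  expect_identical(ls4$environment, "K")
  expect_identical(ls4$region, "KV")
})

test_that("perturbation is zero on self, signed, antisymmetric and clamped", {
  # deletion of G with site W: volume 5 - 1 = +4, clamps to two_more
  ctx <- toy_context("AGWAAAAAAA")
  del_g <- indel_variant("P1", 2, "deletion", "G")
  p <- perturbation(del_g, ctx, "site", "volume", "total")
  expect_equal(p$d, 4)
  expect_identical(p$category, "two_more")
  # the symmetric case
  ctx2 <- toy_context("AWGAAAAAAA")
  del_w <- indel_variant("P1", 2, "deletion", "W")
  p2 <- perturbation(del_w, ctx2, "site", "volume", "total")
  expect_equal(p2$d, -4)
  expect_identical(p2$category, "two_less")

  # self-difference: indel residues identical to the site string
  ctx3 <- toy_context("AKVKVAAAAA")
  del_kv <- indel_variant("P1", 2, "deletion", "KV")
  for (prop in indel_properties) {
    for (mode in c("average", "total")) {
      expect_identical(
        perturbation(del_kv, ctx3, "site", prop, mode)$category, "equal",
        info = paste(prop, mode))
    }
  }

  # antisymmetry: swapping indel residues with site residues negates d
  set.seed(42)
  for (rep in 1:20) {
    aa <- rownames(aa_property_table)
    a <- paste(sample(aa, 2, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 2, replace = TRUE), collapse = "")
    pad <- paste(sample(aa, 6, replace = TRUE), collapse = "")
    ctx_ab <- toy_context(paste0("A", a, b, pad))
    ctx_ba <- toy_context(paste0("A", b, a, pad))
    v_ab <- indel_variant("P1", 2, "deletion", a)
    v_ba <- indel_variant("P1", 2, "deletion", b)
    for (prop in indel_properties) {
      d1 <- perturbation(v_ab, ctx_ab, "site", prop, "total")$d
      d2 <- perturbation(v_ba, ctx_ba, "site", prop, "total")$d
      expect_equal(d1, -d2, info = paste(a, b, prop))
    }
  }
})

test_that("disorder, accessibility and position bins cover their boundaries", {
  mk <- function(disorder = 0, rsa = 0) {
    toy_context(strrep("A", 100), disorder = rep(disorder, 100),
                rsa = rep(rsa, 100))
  }
  v_at <- function(pos) indel_variant("P1", pos, "deletion", "A")
  expect_identical(disorder_category(v_at(50), mk(disorder = 0.1)),
                   "structured")
  expect_identical(disorder_category(v_at(50), mk(disorder = 0.9)),
                   "disorder")
  expect_identical(disorder_category(v_at(50), mk(disorder = 0.4)),
                   "semi_disorder")
  expect_identical(disorder_category(v_at(50), mk(disorder = 0.7)),
                   "semi_disorder")

  expect_identical(rsa_category(v_at(50), mk(rsa = 10)), "fully_buried")
  expect_identical(rsa_category(v_at(50), mk(rsa = 30)), "buried")
  expect_identical(rsa_category(v_at(50), mk(rsa = 60)), "intermediate")
  expect_identical(rsa_category(v_at(50), mk(rsa = 90)), "exposed")
  expect_identical(rsa_category(v_at(50), mk(rsa = 120)), "fully_exposed")
  expect_identical(rsa_category(v_at(50), mk(rsa = 150)), "fully_exposed")

  expect_identical(rip_category(v_at(5), mk()), "n_terminal")
  expect_identical(rip_category(v_at(10), mk()), "n_terminal")
  expect_identical(rip_category(v_at(11), mk()), "middle")
  expect_identical(rip_category(v_at(50), mk()), "middle")
  expect_identical(rip_category(v_at(90), mk()), "c_terminal")
  expect_identical(rip_category(v_at(95), mk()), "c_terminal")
})

test_that("secondary-structure windows detect transitions and break ties to strand", {
  mk_ss <- function(states) {
    toy_context(strrep("A", length(states)), secondary_structure = states)
  }
  v <- indel_variant("P1", 17, "deletion", "A")
  # deletion at 17: site position 18, window 17:19
  all_helix <- mk_ss(c(rep("coil", 16), rep("helix", 14)))
  expect_identical(ss_category(v, all_helix), "helix")
  all_coil <- mk_ss(rep("coil", 30))
  expect_identical(ss_category(v, all_coil), "coil")
  transition <- mk_ss(c(rep("coil", 17), rep("strand", 13)))
  expect_identical(ss_category(v, transition), "two")
  helix_coil <- mk_ss(c(rep("coil", 17), rep("helix", 13)))
  expect_identical(ss_category(v, helix_coil), "two")
  # window {helix, strand, coil}: tie between non-coil states -> strand
  mixed <- mk_ss(c(rep("coil", 16), "helix", "coil", "strand",
                   rep("coil", 11)))
  expect_identical(ss_category(v, mixed), "strand")
})

test_that("length, proline/glycine and overlap flags are straightforward predicates", {
  expect_identical(length_category(indel_variant("P1", 1, "deletion", "N")),
                   "one")
  expect_identical(length_category(indel_variant("P1", 1, "deletion",
                                                 "GPA")), "more_than_one")
  expect_identical(pro_gly_flags(indel_variant("P1", 1, "deletion", "N")),
                   c(has_proline = "false", has_glycine = "false"))
  expect_identical(pro_gly_flags(indel_variant("P1", 1, "deletion", "GPA")),
                   c(has_proline = "true", has_glycine = "true"))
  expect_identical(pro_gly_flags(indel_variant("P1", 1, "deletion", "GG")),
                   c(has_proline = "false", has_glycine = "true"))

  ctx <- toy_context(strrep("A", 30),
                     conserved_residue = c(rep(FALSE, 11), TRUE,
                                           rep(FALSE, 18)),
                     intervals = list(pfam = cbind(5, 20),
                                      block = cbind(12, 20)))
  # deletion at 9-10 -> site span [11, 12]
  v <- indel_variant("P1", 9, "deletion", "AA")
  fl <- overlap_flags(v, ctx)
  expect_identical(unname(fl[c("pfam", "block", "conserved_residue")]),
                   c("true", "true", "true"))
  # deletion at 8 -> site span [9, 10]: disjoint from block, inside pfam
  v2 <- indel_variant("P1", 8, "deletion", "AA")
  fl2 <- overlap_flags(v2, ctx)
  expect_identical(unname(fl2[c("pfam", "block", "conserved_residue")]),
                   c("true", "false", "false"))
  expect_identical(unname(fl2[c("prosite", "uniprot_domain",
                                "macsims_domain")]),
                   c("false", "false", "false"))
})

test_that("annotation is pure, complete and order-independent", {
  sim <- generate_protein_context(120, seed = 8)
  ctx <- sim$context
  v <- indel_variant("synthetic1", 60, "deletion",
                     substr(ctx$sequence, 60, 61), "deleterious")
  fv1 <- annotate_variant(v, ctx)
  fv2 <- annotate_variant(v, ctx)
  expect_identical(fv1, fv2)
  schema <- feature_schema()
  expect_identical(names(fv1), names(schema))
  for (p in names(schema)) {
    expect_true(fv1[[p]] %in% schema[[p]], info = p)
  }
  # cohort annotation: k records, full schema, independent of order
  v2 <- indel_variant("synthetic1", 10, "insertion", "GP", "neutral")
  tab <- annotate_all(list(v, v2), list(synthetic1 = ctx))
  tab_rev <- annotate_all(list(v2, v), list(synthetic1 = ctx))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab[1, -1], tab_rev[2, -1], ignore_attr = TRUE)
})
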