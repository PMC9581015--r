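# Independent oracles: molecular weight is cross-checked against
# seqinr::pmw; the isoelectric point against a grid-scan sign change of a
# charge function written here from the shipped pKa table.

grid_pi <- function(frag) {
  pka <- physicochemical_table("pka")
  chars <- strsplit(frag, "")[[1]]
  charge_at <- function(ph) {
    z <- 1 / (1 + 10^(ph - pka$pka[pka$group == "Nterm"])) -
      1 / (1 + 10^(pka$pka[pka$group == "Cterm"] - ph))
    for (g in c("K", "R", "H"))
      z <- z + sum(chars == g) / (1 + 10^(ph - pka$pka[pka$group == g]))
    for (g in c("D", "E", "C", "Y"))
      z <- z - sum(chars == g) / (1 + 10^(pka$pka[pka$group == g] - ph))
    z
  }
  ph <- seq(0, 14, by = 1e-4)
  ph[which.min(abs(vapply(ph, charge_at, numeric(1))))]
}

test_that("feature values agree with independent recomputation", {
  masses <- physicochemical_table("masses")
  g <- compute_features("G")
  expect_equal(g$molecular_weight,
               masses$mass[masses$residue == "G"] + 18.01528)

  kd <- physicochemical_table("hydrophobicity")
  expect_equal(compute_features("I")$mean_hydrophobicity,
               max(kd$hydropathy))  # isoleucine tops the scale at 4.5

  skip_if_not_installed("seqinr")
  set.seed(4)
  for (i in 1:10) {
    frag <- paste(sample(centerscan:::AA_STANDARD, 14, replace = TRUE),
                  collapse = "")
    expect_equal(compute_features(frag)$molecular_weight,
                 seqinr::pmw(strsplit(frag, "")[[1]]), tolerance = 1e-4)
  }
})

test_that("isoelectric points match a grid-scan root of the charge curve", {
  expect_lt(compute_features("DD")$isoelectric_point, 7)
  expect_gt(compute_features("KK")$isoelectric_point, 7)
  set.seed(14)
  for (frag in c("KACAAAAAAAAAAK", "DDEEYAC", "GGGG",
                 replicate(5, paste(sample(centerscan:::AA_STANDARD, 10,
                                           replace = TRUE), collapse = "")))) {
    expect_equal(compute_features(frag)$isoelectric_point, grid_pi(frag),
                 tolerance = 2e-4)
  }
  # net charge crosses zero at the pI
  expect_equal(net_charge("KACAAAAAAAAAAK",
                          compute_features("KACAAAAAAAAAAK")$isoelectric_point),
               0, tolerance = 1e-5)
})

test_that("ambiguity codes are excluded from averages with a warning", {
  expect_warning(f <- compute_features("GXG"), "ambiguity")
  expect_equal(f$molecular_weight, compute_features("GG")$molecular_weight)
  expect_error(suppressWarnings(compute_features("XX")), "no standard")
})

test_that("reference statistics floor degenerate spreads", {
  one <- reference_stats("KACAAAAAAAAAAK")
  f <- compute_features("KACAAAAAAAAAAK")
  expect_equal(unname(one$mean["molecular_weight"]), f$molecular_weight)
  expect_equal(unname(one$sd),
               unname(1e-6 * abs(one$mean) + 1e-9))
  two <- reference_stats(c("GGG", "GGG"))
  expect_equal(unname(two$sd), unname(1e-6 * abs(two$mean) + 1e-9))

  # 10 generated 14-mers: means match a spreadsheet-style recomputation
  set.seed(77)
  refs <- replicate(10, sample_motif_instance(builtin_motifs()[[1]]$pattern))
  rs <- reference_stats(refs)
  expect_equal(rs$n_reference, 10L)
  mw <- vapply(refs, function(s) compute_features(s)$molecular_weight,
               numeric(1))
  expect_equal(unname(rs$mean["molecular_weight"]), sum(mw) / 10)
  expect_equal(unname(rs$sd["molecular_weight"]),
               sqrt(sum((mw - mean(mw))^2) / 9))
  expect_error(reference_stats(character()), "empty")
})

test_that("scores anchor at 1 on the mean and 0 at c sigma", {
  set.seed(5)
  refs <- replicate(8, sample_motif_instance(builtin_motifs()[[2]]$pattern))
  rs <- reference_stats(refs)
  at_mean <- score_hit(as.list(rs$mean), rs)
  expect_equal(unname(at_mean$scores), rep(1, 3))
  expect_equal(at_mean$overall, 1)
  expect_true(at_mean$selected)

  off <- as.list(rs$mean)
  off$isoelectric_point <- rs$mean[["isoelectric_point"]] +
    3 * rs$sd[["isoelectric_point"]]
  card <- score_hit(off, rs, c = 3)
  expect_equal(unname(card$scores["isoelectric_point"]), 0)
  expect_equal(unname(card$classes["isoelectric_point"]), "red")
  expect_false(card$selected)

  # symmetric deviations score identically
  up <- as.list(rs$mean); up$molecular_weight <- rs$mean[["molecular_weight"]] + 50
  dn <- as.list(rs$mean); dn$molecular_weight <- rs$mean[["molecular_weight"]] - 50
  expect_equal(score_hit(up, rs)$scores, score_hit(dn, rs)$scores)
})

test_that("scores are bounded and non-increasing in deviation", {
  set.seed(15)
  refs <- replicate(6, sample_motif_instance(builtin_motifs()[[1]]$pattern))
  rs <- reference_stats(refs)
  deltas <- seq(0, 6, by = 0.5)
  sc <- vapply(deltas, function(d) {
    f <- as.list(rs$mean)
    f$mean_hydrophobicity <- rs$mean[["mean_hydrophobicity"]] +
      d * rs$sd[["mean_hydrophobicity"]]
    score_hit(f, rs)$scores[["mean_hydrophobicity"]]
  }, numeric(1))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("the selection rule is enforced verbatim", {
  # synthetic score cards across the rule's truth table
  make_card <- function(scores, green = 0.6, red = 0.3) {
    rs <- structure(list(
      mean = stats::setNames(rep(0, 3), centerscan:::SCORED_FEATURES),
      sd = stats::setNames(rep(1, 3), centerscan:::SCORED_FEATURES),
      n_reference = 1L, provenance = NULL), class = "reference_stats")
    # deviation d gives score 1 - d/3 under c = 3
    f <- as.list(stats::setNames(3 * (1 - scores),
                                 centerscan:::SCORED_FEATURES))
    score_hit(f, rs, c = 3, green = green, red = red)
  }
  expect_true(make_card(c(1, 1, 1))$selected)
  expect_true(make_card(c(0.9, 0.7, 0.45))$selected)     # 2 greens, 1 amber
  expect_false(make_card(c(0.9, 0.5, 0.5))$selected)     # only 1 green
  expect_false(make_card(c(1, 1, 0.1))$selected)         # red present
  expect_false(make_card(c(0.65, 0.65, 0.31))$selected)  # overall amber
  card <- make_card(c(0.9, 0.7, 0.45))
  expect_true(card$overall_class == "green" && card$n_green >= 2 &&
                card$n_red == 0)
})

test_that("reference-drawn fragments outscore shifted ones", {
  set.seed(25)
  refs <- replicate(15, sample_motif_instance(builtin_motifs()[[1]]$pattern))
  rs <- reference_stats(refs)
  in_dist <- replicate(10, sample_motif_instance(builtin_motifs()[[1]]$pattern))
  score_of <- function(s) score_hit(compute_features(s), rs)$overall
  mean_in <- mean(vapply(in_dist, score_of, numeric(1)))
  shifted <- structure(rs, class = "reference_stats")
  shifted$mean <- rs$mean + 5 * rs$sd
  mean_out <- mean(vapply(in_dist, function(s)
    score_hit(compute_features(s), shifted)$overall, numeric(1)))
  expect_gt(mean_in, mean_out)
})

test_that("hit tables score and rank deterministically", {
  pl <- plant_instances(random_proteome(20, 300, seed = 41),
                        builtin_motifs()[[1]], k = 5, seed = 42,
                        with_downstream_DE = TRUE)
  hits <- quiet_scan(pl$proteome, builtin_motifs()[1])
  hits <- annotate_downstream_acidic(hits, pl$proteome)
  set.seed(43)
  refs <- replicate(12, sample_motif_instance(builtin_motifs()[[1]]$pattern))
  scored <- score_hits(hits, reference_stats(refs))
  expect_true(all(scored$overall_score >= 0 & scored$overall_score <= 1))
  expect_true(all(scored$cation_binding ==
                    !is.na(scored$downstream_acidic_offset)))
  ranked <- rank_hits(scored)
  expect_true(all(diff(ranked$overall_score[!ranked$selected]) <= 1e-12) ||
                any(ranked$selected))
  # selected block first, then descending overall
  sel_idx <- which(ranked$selected)
  if (length(sel_idx)) expect_equal(sel_idx, seq_along(sel_idx))
  for (grp in split(seq_len(nrow(ranked)), ranked$selected))
    expect_true(all(diff(ranked$overall_score[grp]) <= 1e-12))
})

test_that("rank_hits tie-breaks on greens, then seq_id and start", {
  base <- data.frame(seq_id = c("b", "a", "a"), start = c(5L, 9L, 2L),
                     overall_score = c(0.8, 0.8, 0.8),
                     n_green = c(3L, 2L, 2L),
                     selected = c(TRUE, TRUE, TRUE))
  r <- rank_hits(base)
  expect_equal(r$seq_id, c("b", "a", "a"))
  expect_equal(r$start, c(5L, 2L, 9L))

  two <- data.frame(seq_id = c("a", "b"), start = c(1L, 1L),
                    overall_score = c(0.4, 0.9), n_green = c(1L, 3L),
                    selected = c(FALSE, FALSE))
  expect_equal(rank_hits(two)$overall_score, c(0.9, 0.4))
})
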