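mini_condition <- function(name) {
  read_condition(system.file("extdata", paste0(tolower(name), "_mini.yaml"),
                             package = "attractorscreen"))
}

test_that("risk-factor conditions rewire rules and return residual pins", {
  mini <- build_mini_ad_network()
  # a pin-only loss-of-function condition propagates as activity 0
  lof <- risk_factor_condition("PTEN_LOF", pins = c(PTEN = 0))
  ap <- apply_risk_factor(mini, lof)
  expect_equal(ap$network$rules, mini$rules)
  ls <- enumerate_landscape(ap$network, ap$pins)
  expect_identical(unname(node_activity(ls)["PTEN"]), 0)

  # the normal condition leaves rule truth tables untouched
  nrm <- risk_factor_condition("normal")
  apn <- apply_risk_factor(mini, nrm)
  expect_equal(apn$network$rules, mini$rules)
  expect_length(apn$pins, 0)

  # overriding the AKT arm to constant 0 rewires the landscape: the
  # mTORC1 brake never engages, so autophagy rises and attractors shift
  ko <- risk_factor_condition("AKT_KO", overrides = c(PI3K_AKT = "0"))
  apk <- apply_risk_factor(mini, ko)
  base_ls <- enumerate_landscape(mini)
  after_ls <- enumerate_landscape(apk$network)
  expect_false(identical(landscape_keys(after_ls), landscape_keys(base_ls)))
  expect_gt(node_activity(after_ls)["autophagy"],
            node_activity(base_ls)["autophagy"])

  expect_error(
    apply_risk_factor(mini, risk_factor_condition("x", pins = c(NOPE = 1))),
    "NOPE")
  expect_error(risk_factor_condition("x", pins = c(A = 0),
                                     overrides = c(A = "1")),
               "both pinned and overridden")
})

test_that("single screens enumerate exactly the eligible candidates", {
  mini <- build_mini_ad_network()
  cond <- mini_condition("APOE4")
  sc <- screen_single(mini, cond)
  # 18 nodes - 5 outputs - 1 input - 2 condition-overridden nodes
  expect_equal(nrow(sc$entries), 18 - 5 - 1 - 2)
  expect_false(any(c("ROS", "Abeta", "WNT_can", "mTORC1") %in%
                     sc$entries$targets))
  # ranked by descending score with rank column consistent
  expect_true(all(diff(sc$entries$score) <= 0))
  expect_equal(sc$entries$rank, seq_len(nrow(sc$entries)))
  expect_equal(sc$entries$delta, sc$entries$score - sc$baseline$score)
})

test_that("PTEN inhibition rescues p-tau under the ApoE4-like condition", {
  mini <- build_mini_ad_network()
  cond <- mini_condition("APOE4")
  ap <- apply_risk_factor(mini, cond)
  base <- enumerate_landscape(ap$network, ap$pins)
  pt_base <- node_activity(base)["ptau"]
  lsp <- enumerate_landscape(ap$network, perturbation(c(PTEN = 0)))
  expect_lt(node_activity(lsp)["ptau"], pt_base)
  # and the screen records exactly these values
  sc <- screen_single(mini, cond)
  e <- sc$entries[sc$entries$targets == "PTEN", ]
  expect_equal(e$ptau, unname(node_activity(lsp)["ptau"]))
  expect_equal(e$score, phenotype_score(lsp))
})

test_that("double screens cover all pairs and reproduce the autophagy rescue", {
  mini <- build_mini_ad_network()
  sc <- screen_double(mini)
  m <- 18 - 5 - 1
  expect_equal(nrow(sc$entries), choose(m, 2))
  # pinning PTEN and mTORC1 together restores autophagy without raising p-tau
  base_act <- node_activity(sc$baseline$landscape)
  e <- sc$entries[sc$entries$targets == "PTEN+mTORC1", ]
  expect_equal(nrow(e), 1)
  expect_gte(e$autophagy, unname(base_act["autophagy"]))
  expect_lte(e$ptau, unname(base_act["ptau"]))
  # the pair budget is enforced
  expect_error(screen_double(mini, max_pairs = 10), "max_pairs")
})

test_that("screens match brute-force independent re-evaluation on a small fixture", {
  net <- generate_random_network(7, k = 2, n_outputs = 5, seed = 77)
  sc <- screen_single(net)
  cands <- setdiff(net$nodes, c(output_nodes(net), input_nodes(net)))
  for (cand in cands) {
    oracle <- r_landscape(net, c(stats::setNames(0L, cand)))
    e <- sc$entries[sc$entries$targets == cand, ]
    # recompute the score from the oracle basin counts
    ls <- enumerate_landscape(net, perturbation(stats::setNames(0, cand)))
    got <- stats::setNames(ls$basin_count,
                           vapply(ls$attractors, `[[`, "", "id"))
    expect_equal(got[names(oracle)], oracle)
    expect_equal(e$score, phenotype_score(ls))
  }
})

test_that("ranking is a stable total order with the documented tie-breaks", {
  mini <- build_mini_ad_network()
  a <- screen_double(mini, sampling = screen_sampling(seed = 3))
  b <- screen_double(mini, sampling = screen_sampling(seed = 3))
  expect_identical(a$entries, b$entries)
  ties <- split(a$entries$targets, a$entries$score)
  for (grp in ties)
    expect_identical(grp, sort(grp))  # lexicographic within equal scores
})

test_that("a zero-influence node adds nothing to a pair", {
  # iso regulates only itself: pinning it cannot move anything downstream
  net <- boolean_network(list(iso = "iso", A = "B", B = "!A", out = "A"),
                         roles = c(out = "output"),
                         phenotypes = c(out = "Abeta"))
  cfg <- phenotype_config(weights = c(Abeta = 30),
                          direction = c(Abeta = "low"))
  # iso has no path to out in this reduced rule set
  single_A <- phenotype_score(
    enumerate_landscape(net, perturbation(c(A = 0))), cfg)
  pair <- phenotype_score(
    enumerate_landscape(net, perturbation(c(A = 0, iso = 0))), cfg)
  expect_equal(pair, single_A)
  # and a no-influence single pin has delta exactly 0
  base <- phenotype_score(enumerate_landscape(net), cfg)
  iso_only <- phenotype_score(
    enumerate_landscape(net, perturbation(c(iso = 0))), cfg)
  expect_equal(iso_only - base, 0)
})

test_that("the normal condition reproduces the baseline landscape bit-for-bit", {
  mini <- build_mini_ad_network()
  plain <- enumerate_landscape(mini)
  sc <- screen_single(mini, condition = NULL)
  expect_identical(landscape_keys(sc$baseline$landscape),
                   landscape_keys(plain))
  expect_identical(sc$baseline$landscape$basin_count, plain$basin_count)
})

test_that("screen tables export to TSV", {
  sc <- screen_single(build_mini_ad_network(), mini_condition("LPL"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(sc, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(sc$entries))
  expect_equal(tab$targets, sc$entries$targets)
})
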