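alphabet <- c("R", "B", "Y")
cnt <- function(R = 0, B = 0, Y = 0) c(R = R, B = B, Y = Y)

with_seed_draws <- function(seed, n, rule, current, neighbors) {
  set.seed(seed)
  vapply(seq_len(n), function(i) decide_position(rule, current, neighbors),
         character(1))
}

test_that("majority picks the modal color and splits ties uniformly", {
  maj <- decision_rule("majority")
  expect_equal(rule_distribution(maj, "R", cnt(B = 3, Y = 1)),
               c(R = 0, B = 1, Y = 0))
  expect_equal(rule_distribution(maj, "R", cnt(B = 2, Y = 2)),
               c(R = 0, B = 0.5, Y = 0.5))
  # tie-break by random election: observed frequencies near 1/2
  draws <- with_seed_draws(101, 4000, maj, "R", c("B", "B", "Y", "Y"))
  expect_equal(mean(draws == "B"), 0.5, tolerance = 0.05)
  expect_true(all(draws %in% c("B", "Y")))
})

test_that("voter draws from the neighborhood; random ignores it", {
  voter <- decision_rule("voter")
  expect_equal(rule_distribution(voter, "R", cnt(R = 1, B = 3)),
               c(R = 0.25, B = 0.75, Y = 0))
  distinct <- decision_rule("voter", voter_mode = "distinct")
  expect_equal(rule_distribution(distinct, "R", cnt(R = 1, B = 3)),
               c(R = 0.5, B = 0.5, Y = 0))
  rnd <- decision_rule("random")
  expect_equal(rule_distribution(rnd, "R", cnt(B = 4)),
               c(R = 1, B = 1, Y = 1) / 3)
})

test_that("voter and majority fall back to uniform with a silent neighborhood", {
  for (name in c("voter", "majority")) {
    p <- rule_distribution(decision_rule(name), NA, cnt())
    expect_equal(unname(p), rep(1 / 3, 3))
  }
})

test_that("every rule yields a normalized, permutation-equivariant distribution", {
  tab <- transition_table(sample_rule_events(decision_rule("majority"), 3000,
                                             seed = 7), min_count = 1)
  rules <- list(decision_rule("majority"), decision_rule("voter"),
                decision_rule("voter", voter_mode = "distinct"),
                decision_rule("random"),
                decision_rule("bayesian", s = 0.57, a = 0.19),
                decision_rule("empirical_table", table = tab))
  set.seed(9)
  for (rule in rules) {
    for (i in 1:40) {
      counts <- stats::setNames(sample(0:4, 3, replace = TRUE), alphabet)
      cur <- sample(c(alphabet, NA), 1)
      p <- rule_distribution(rule, cur, counts)
      expect_prob_vector(p)
      perm <- sample(alphabet)
      pc <- counts; names(pc) <- perm
      pc <- pc[alphabet]
      pcur <- if (is.na(cur)) NA else perm[match(cur, alphabet)]
      pp <- rule_distribution(rule, pcur, pc)
      if (rule$name != "empirical_table") {
        # empirical tables are estimated, hence not exactly color-symmetric
        expect_equal(unname(pp[perm]), unname(p[alphabet]), tolerance = 1e-12)
      }
    }
  }
})

test_that("empirical-table lookups use the estimated curves and fall back to uniform", {
  ev <- data.frame(from = c("R", "R"), to = c("R", "B"),
                   n_R = c(1L, 1L), n_B = c(2L, 2L), n_Y = c(1L, 1L),
                   k_eff = c(4L, 4L))
  tab <- transition_table(ev, k = 4, min_count = 1)
  rule <- decision_rule("empirical_table", table = tab)
  # stay weight P(R|R; n_R=1) = 1/2, switch weights P(B|.;2) = 1/2, P(Y|.;1) = 0
  expect_equal(rule_distribution(rule, "R", cnt(R = 1, B = 2, Y = 1)),
               c(R = 0.5, B = 0.5, Y = 0))
  # counts hitting an undefined (never observed) cell: uniform fallback
  expect_equal(unname(rule_distribution(rule, "R", cnt(R = 4))), rep(1 / 3, 3))
})

test_that("decide_position validates inputs", {
  expect_error(decide_position(decision_rule("majority"), "R", c("B", "G")),
               "outside alphabet")
  expect_error(decision_rule("least_squares"), "arg")
  expect_error(decision_rule("bayesian"), "requires parameter s")
  expect_error(decision_rule("empirical_table"), "requires a transition_table")
})
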