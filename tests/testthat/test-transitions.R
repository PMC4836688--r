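# Independent brute-force tally of transition events for a log: plain
# loops over proposals, kept deliberately separate from the package's
# implementation.
naive_transitions <- function(log) {
  ev <- log$events
  out <- NULL
  for (r in seq_len(nrow(ev))) {
    j <- ev$player[r]
    prev <- ev[ev$player == j & ev$time_s < ev$time_s[r], ]
    if (!nrow(prev)) next
    c1 <- strsplit(prev$code[nrow(prev)], "")[[1]]
    c2 <- strsplit(ev$code[r], "")[[1]]
    nbs <- setdiff(unique(as.vector(
      log$network$edges[log$network$edges[, 1] == j |
                        log$network$edges[, 2] == j, ])), j)
    for (pos in setdiff(seq_len(log$setup$L), log$setup$reveals[[j]])) {
      n <- c(R = 0, B = 0, Y = 0)
      k_eff <- 0
      for (nb in nbs) {
        hist <- ev[ev$player == nb & ev$time_s < ev$time_s[r], ]
        if (!nrow(hist)) next
        col <- strsplit(hist$code[nrow(hist)], "")[[1]][pos]
        n[col] <- n[col] + 1
        k_eff <- k_eff + 1
      }
      out <- rbind(out, data.frame(
        player = j, position = pos, time_s = ev$time_s[r],
        from = c1[pos], to = c2[pos],
        n_R = unname(n["R"]), n_B = unname(n["B"]), n_Y = unname(n["Y"]),
        k_eff = k_eff
      ))
    }
  }
  out
}

test_that("transition extraction matches a brute-force tally on a hand-built game", {
  log <- two_player_log()
  got <- extract_transitions(log)
  # (3 - 1) proposals x 7 unknown positions for player 1, 1 x 7 for player 2
  expect_equal(sum(got$player == 1), 14)
  expect_equal(sum(got$player == 2), 7)
  expect_true(all(!got$position[got$player == 1] %in% 1:3))
  expect_true(all(!got$position[got$player == 2] %in% 8:10))
  want <- naive_transitions(log)
  ord <- function(d) d[order(d$time_s, d$player, d$position), ]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
  # spot-check one hand-tallied event: player 1 deciding position 8 at t=60
  # sees player 2's t=50 code "BBBBBBBBYR" (B at position 8)
  e <- got[got$player == 1 & got$position == 8 & got$time_s == 60, ]
  expect_equal(e$from, "B")  # from "RBYYYYYBBB"
  expect_equal(e$to, "B")    # to the target "RBYRRYBBYR"
  expect_equal(c(e$n_R, e$n_B, e$n_Y), c(0, 1, 0))
})

test_that("extraction agrees with brute force on simulated games", {
  for (seed in c(5, 6)) {
    log <- tiny_log(seed, rule = decision_rule("voter"))
    got <- extract_transitions(log)
    want <- naive_transitions(log)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      ord <- function(d) d[order(d$time_s, d$player, d$position), ]
      expect_equal(ord(got), ord(want), ignore_attr = TRUE)
    }
  }
})

test_that("change-to-color estimates are event ratios with undefined empty cells", {
  ev <- data.frame(from = c("B", "Y", "B"), to = c("R", "R", "R"),
                   n_R = c(2L, 2L, 0L), n_B = c(1L, 1L, 3L), n_Y = c(1L, 1L, 1L),
                   k_eff = 4L)
  tc <- estimate_prob_to_color(ev)
  expect_equal(tc$p[tc$color == "R" & tc$n == 2], 1)   # both n_R=2 events end R
  expect_equal(tc$p[tc$color == "R" & tc$n == 0], 1)
  expect_true(is.na(tc$p[tc$color == "R" & tc$n == 4]))  # no events: undefined
  expect_equal(tc$count[tc$color == "B" & tc$n == 1], 2)
  expect_equal(tc$p[tc$color == "B" & tc$n == 1], 0)
  # single event: one defined cell with probability 1
  one <- estimate_prob_to_color(ev[1, ])
  expect_equal(one$p[one$color == "R" & one$n == 2], 1)
  expect_equal(sum(!is.na(one$p) & one$p == 1), 1)
})

test_that("stay and switch-away probabilities are complete per configuration", {
  ev <- sample_rule_events(decision_rule("bayesian", s = 0.57, a = 0.19),
                           20000, seed = 31)
  # group by (prior, full configuration): empirical final-color shares sum to 1
  key <- paste(ev$from, ev$n_R, ev$n_B, ev$n_Y)
  set.seed(1)
  for (u in sample(unique(key), 10)) {
    to <- ev$to[key == u]
    expect_equal(sum(table(factor(to, c("R", "B", "Y")))) / length(to), 1)
    shares <- as.vector(table(factor(to, c("R", "B", "Y")))) / length(to)
    expect_equal(sum(shares), 1)
  }
  cond <- estimate_conditional(ev)
  expect_true(all(cond$stay_agg$p >= 0 & cond$stay_agg$p <= 1, na.rm = TRUE))
  # every event lands in exactly one stay-curve conditioning cell
  expect_equal(sum(cond$stay$count), nrow(ev))
})

test_that("transition tables are color-permutation equivariant", {
  ev <- sample_rule_events(decision_rule("majority"), 5000, seed = 8)
  tab <- estimate_prob_to_color(ev)
  perm <- c(R = "B", B = "Y", Y = "R")
  pe <- ev
  pe$from <- unname(perm[ev$from])
  pe$to <- unname(perm[ev$to])
  pe$n_B <- ev$n_R; pe$n_Y <- ev$n_B; pe$n_R <- ev$n_Y
  ptab <- estimate_prob_to_color(pe)
  for (X in c("R", "B", "Y")) {
    expect_equal(ptab$p[ptab$color == perm[X]], tab$p[tab$color == X])
    expect_equal(ptab$count[ptab$color == perm[X]], tab$count[tab$color == X])
  }
})

test_that("tables estimated from a known rule converge to its conditionals", {
  # random rule: every conditional is exactly 1/3
  ev <- sample_rule_events(decision_rule("random"), 60000, seed = 9)
  tab <- transition_table(ev)
  expect_lt(max(abs(tab$to_color$p - 1 / 3), na.rm = TRUE), 0.02)
  # majority rule: compare against an independent enumeration of the rule
  true_majority <- function(nR, nB, nY, X) {
    v <- c(R = nR, B = nB, Y = nY)
    top <- names(v)[v == max(v)]
    if (X %in% top) 1 / length(top) else 0
  }
  ev2 <- sample_rule_events(decision_rule("majority"), 60000, seed = 10)
  tab2 <- estimate_prob_to_color(ev2)
  for (X in c("R", "B", "Y")) {
    nX <- ev2[[paste0("n_", X)]]
    for (n in 0:4) {
      sel <- nX == n
      truth <- mean(mapply(true_majority, ev2$n_R[sel], ev2$n_B[sel],
                           ev2$n_Y[sel], X))
      est <- tab2$p[tab2$color == X & tab2$n == n]
      expect_equal(est, truth, tolerance = 0.06)
    }
  }
})

test_that("revealed positions never generate transition events", {
  log <- tiny_log(77, rule = decision_rule("majority"))
  ev <- extract_transitions(log)
  for (r in seq_len(nrow(ev))) {
    expect_false(ev$position[r] %in% log$setup$reveals[[ev$player[r]]])
  }
})
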