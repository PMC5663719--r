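test_that("spectral costs are absolute semitone distances", {
  expect_equal(spectral_costs(0, c(-2, 2)), matrix(c(2, 2), 1))
  expect_equal(spectral_costs(c(0, 1), c(2, -1)),
               matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(diag(spectral_costs(c(0, 3), c(0, 3))), c(0, 0))
})

test_that("the linear assignment solver finds forced optima", {
  r <- solve_lap(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(r$mapping, c(1, 2))
  expect_equal(r$spectral_cost, 2)
  # the two-syllable/two-target cost geometry of the close-vs-far tasks
  r4 <- solve_lap(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(r4$mapping, c(2, 1))
  expect_equal(r4$spectral_cost, 2)
  # empty problem
  expect_equal(solve_lap(matrix(numeric(0), 0, 0))$spectral_cost, 0)
})

test_that("brute force handles trivial cases and refuses big ones", {
  expect_equal(solve_lap_bruteforce(matrix(5))$spectral_cost, 5)
  m <- diag(c(0, 0, 0)) + 1 - diag(3)
  expect_equal(solve_lap_bruteforce(m)$mapping, 1:3)
  expect_error(solve_lap_bruteforce(matrix(1, 9, 9)), "limited to 8")
})

test_that("solver and brute force agree on random rectangular problems", {
  set.seed(77)
  for (rep in 1:60) {
    nt <- sample(2:5, 1)
    nm <- nt + sample(0:2, 1)
    cost <- matrix(runif(nm * nt, 0, 10), nm, nt)
    a <- solve_lap(cost)
    b <- solve_lap_bruteforce(cost)
    expect_equal(a$spectral_cost, b$spectral_cost, tolerance = 1e-9)
    expect_equal(a$mapping, b$mapping)
  }
})

test_that("sequence cost counts unacquired target transitions", {
  t1 <- fixture_tasks$task1
  # identity-order mapping: the learner sings A B C+ repeats; enumerating
  # bigrams of ABC+-repeats {A>B, B>C+, C+>A} against the target's
  # {A>C+, C+>B, B>A} shows all three must still be acquired
  expect_equal(sequence_cost(c(A = "A", B = "B", C = "C+2"),
                             t1$source, t1$target), 3)
  # matched order: zero
  expect_equal(sequence_cost(c(A = "A", B = "B"), c("A", "B"),
                             c("A", "B")), 0)
  # single-syllable target motif: no bigrams to acquire
  expect_equal(sequence_cost(c(A = "A"), "A", "A"), 0)
})

test_that("combined cost reduces to LAP at lambda zero and flips for large lambda", {
  t4 <- fixture_tasks$task4.1
  q0 <- qap_minimize(t4, lambda = 0)
  expect_equal(q0$mapping, c("B" = "B-1", "B+1" = "B+2"))
  expect_equal(q0$total, q0$spectral)
  expect_equal(q0$spectral, solve_lap(assignment_problem(t4))$spectral_cost)
  # greedy mapping breaks all four target transitions (k = 4), so the
  # optimum flips to the sequence-preserving mapping once
  # 2 + lambda * 4 > 4, i.e. lambda > 1/2
  expect_equal(qap_total(t4, c("B" = "B-1", "B+1" = "B+2"), 0)$sequence, 4)
  q_hi <- qap_minimize(t4, lambda = 0.6)
  expect_equal(q_hi$mapping, c("B" = "B+2", "B+1" = "B-1"))
  expect_equal(q_hi$sequence, 0)
  q_lo <- qap_minimize(t4, lambda = 0.4)
  expect_equal(q_lo$mapping, c("B" = "B-1", "B+1" = "B+2"))
  # a matched source/target pair costs nothing at the identity
  src <- fixture_tasks$task1$source
  same <- imitation_task("id", src, src,
                         data.frame(source_label = character(),
                                    target_label = character(),
                                    shift = numeric()))
  expect_equal(qap_total(same, c(C = "C"), 1)$total, 0)
})

test_that("musical chairs matches both equidistant targets via one call", {
  t3 <- fixture_tasks$task3
  for (seed in 1:25) {
    res <- musical_chairs(t3, tie_seed = seed,
                          call_pitches = c(call1 = -3.5))
    m <- res$mapping
    expect_false(any(is.na(m)))
    expect_equal(sort(unname(m)), c(1, 2))       # both targets occupied
    # the focal syllable claims exactly one target; the call the other
    expect_equal(sum(res$log$event == "recruit"), 1)
    expect_equal(res$log$motor[res$log$event == "recruit"], "call1")
  }
})

test_that("equidistant targets are chosen in even proportion over tie seeds", {
  t3 <- fixture_tasks$task3
  picks <- vapply(1:200, function(s) {
    m <- musical_chairs(t3, tie_seed = s, call_pitches = c(call1 = -3.5))
    unname(m$mapping["B"])
  }, numeric(1))
  frac_down <- mean(picks == 1)  # target 1 is the downward variant
  expect_lt(abs(frac_down - 0.5), 0.07)
})

test_that("musical chairs picks the spectrally closer targets in the 1-vs-2 task", {
  for (tk in list(fixture_tasks$task4.1, fixture_tasks$task4.2)) {
    prob <- assignment_problem(tk)
    res <- musical_chairs(prob, tie_seed = 1)
    # each motor syllable ends on its 1-semitone target
    d <- prob$cost[cbind(seq_along(res$mapping), res$mapping)]
    expect_equal(d, c(1, 1))
  }
})

test_that("musical chairs is the identity on a matched problem", {
  prob <- structure(list(motor_labels = c("X", "Y"),
                         motor_pitches = c(0, 3),
                         motor_positions = c(1L, 2L),
                         target_labels = c("X", "Y"),
                         target_pitches = c(0, 3),
                         target_positions = c(1L, 2L),
                         cost = spectral_costs(c(0, 3), c(0, 3))),
                    class = "assignment_problem")
  res <- musical_chairs(prob)
  expect_equal(unname(res$mapping), c(1, 2))
  expect_equal(res$spectral_cost, 0)
  expect_false(any(res$log$event == "displaced"))
})

test_that("musical chairs flags vacancies when no call is available", {
  t3 <- fixture_tasks$task3
  expect_warning(res <- musical_chairs(t3, tie_seed = 1), "vacant")
  expect_true(res$partial)
  expect_true(any(res$log$event == "vacant"))
})

test_that("chairs assignments are injective, target-complete and near-optimal", {
  set.seed(5)
  n_opt <- 0
  for (rep in 1:100) {
    nt <- sample(2:5, 1)
    nm <- nt + sample(0:2, 1)
    prob <- structure(list(
      motor_labels = paste0("m", seq_len(nm)),
      motor_pitches = runif(nm, -6, 6),
      motor_positions = seq_len(nm),
      target_labels = paste0("t", seq_len(nt)),
      target_pitches = runif(nt, -6, 6),
      target_positions = seq_len(nt), cost = NULL),
      class = "assignment_problem")
    prob$cost <- spectral_costs(prob$motor_pitches, prob$target_pitches)
    ch <- musical_chairs(prob, tie_seed = rep)
    matched <- ch$mapping[!is.na(ch$mapping)]
    expect_equal(sort(unname(matched)), seq_len(nt))  # injective, complete
    lap <- solve_lap(prob$cost)
    expect_gte(ch$spectral_cost, lap$spectral_cost - 1e-9)
    if (ch$spectral_cost <= lap$spectral_cost + 1e-9) n_opt <- n_opt + 1
  }
  # greedy competition usually attains the optimum on scattered targets
  expect_gt(n_opt / 100, 0.5)
})

test_that("strategy predictions follow their defining rules", {
  t1 <- fixture_tasks$task1
  # global: match by motif position, so the pitch error lands on the
  # position-2 occupant, not on the focal syllable
  g <- strategy_predict(t1, "global")
  expect_equal(g[["B"]], "C+2")
  expect_equal(g[["C"]], "B")
  # greedy: the focal syllable takes its pitch target regardless of order
  gr <- strategy_predict(t1, "greedy")
  expect_equal(gr[["C"]], "C+2")
  # chunk on the two-equidistant-target task: the bigram context selects
  # the sequence-consistent target
  ch <- strategy_predict(fixture_tasks$task3, "chunk",
                         call_pitches = c(call1 = -3.5))
  expect_equal(ch[["B"]], "B-2")
  expect_error(strategy_predict(t1, "positional"), "arg")
})
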