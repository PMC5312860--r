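geo <- build_default_pore()
ccfg <- contact_config()

test_that("contact detection matches constructed distances", {
  top <- build_surrogate_topology(geo)
  ref <- attr(top, "ref_coords")
  # place the solute 0.35 nm above one D45 C-alpha: only D45 in contact
  d45 <- which(top$resno == 45 & top$chain == "A")
  coords <- ref
  for (i in which(top$solute))
    coords[i, ] <- ref[d45, ] + c(0, 0, 0.35)
  hits <- detect_contacts(coords, top, ccfg)
  expect_identical(hits, "D45")
  # everything far away: no contacts
  for (i in which(top$solute)) coords[i, ] <- c(50, 50, 50)
  expect_length(detect_contacts(coords, top, ccfg), 0)
})

test_that("contact detection and the distance kernel agree with brute force", {
  top <- fixture_small_topology(geo)
  set.seed(61)
  centres <- cbind(rnorm(40, 0, 0.8), rnorm(40, 0, 0.8),
                   runif(40, -0.5, 1))
  traj <- fixture_trajectory(centres, top)
  series <- porecap:::residue_distance_series(traj, ccfg)
  sol <- which(top$solute); prot <- which(!top$solute)
  for (f in seq_len(nrow(centres))) {
    coords <- matrix(traj$coords[f, ], ncol = 3, byrow = TRUE)
    # brute force: explicit all-pairs loop
    best <- Inf
    for (i in sol) for (j in prot)
      best <- min(best, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    expect_equal(unname(series[f, "K8"]), best, tolerance = 1e-12)
    expect_identical(detect_contacts(coords, top, ccfg),
                     if (best <= ccfg$cutoff) "K8" else character(0))
  }
})

test_that("residence events are maximal runs without gap bridging", {
  ev <- residence_events(c(TRUE, TRUE, TRUE, FALSE, TRUE), 10)
  expect_equal(ev$duration, c(30, 10))
  expect_equal(ev$start, c(0, 40))
  expect_equal(nrow(residence_events(rep(FALSE, 5), 10)), 0)
  expect_error(residence_events(logical(0), 10), "empty")
})

test_that("duration thresholds are strict at the 100 ps and 1 ns boundaries", {
  # a run of exactly 10 frames at 10 ps lasts 100 ps: NOT transient
  series <- c(rep(TRUE, 10), rep(FALSE, 5))
  ev <- residence_events(series, 10)
  expect_equal(ev$duration, 100)
  expect_false(ev$duration < ccfg$transient_max_duration)
  # exactly 1 ns is NOT stable; 1 ns + one frame is
  ev2 <- residence_events(rep(TRUE, 100), 10)   # 1000 ps
  expect_false(ev2$duration > ccfg$stable_min_duration)
  ev3 <- residence_events(rep(TRUE, 101), 10)   # 1010 ps
  expect_true(ev3$duration > ccfg$stable_min_duration)
})

test_that("event durations conserve the in-contact frame count exactly", {
  set.seed(71)
  for (i in 1:50) {
    s <- runif(200) < runif(1)
    if (!any(s)) s[1] <- TRUE
    ev <- residence_events(s, 10)
    expect_identical(sum(ev$duration), 10 * sum(s))
  }
})

test_that("profiles bound fractions and event totals by the trajectory", {
  top <- fixture_small_topology(geo)
  set.seed(81)
  traj <- fixture_trajectory(cbind(rnorm(80, 0, 0.5), rnorm(80, 0, 0.5),
                                   runif(80, -0.3, 0.5)), top)
  prof <- contact_profile(traj, ccfg, geo)
  expect_true(all(prof$contact_fraction >= 0 & prof$contact_fraction <= 1))
  for (r in prof$residue) {
    ev <- attr(prof, "events")[[r]]
    expect_lte(sum(ev$duration),
               traj$frame_interval * nrow(traj$coords))
    expect_equal(sum(ev$duration) / (10 * 80),
                 prof$contact_fraction[prof$residue == r])
  }
})

test_that("group summaries apply the strict 5% extended threshold", {
  top <- fixture_small_topology(geo)
  # run A: in contact 10% of frames; run B: 1 frame in 500
  near <- c(1.3, 0, 0.1); far <- c(5, 5, 5)  # 0.1 nm from a K8 C-alpha
  mk <- function(n_near, n_far) fixture_trajectory(
    rbind(matrix(rep(near, n_near), ncol = 3, byrow = TRUE),
          matrix(rep(far, n_far), ncol = 3, byrow = TRUE)), top)
  profs <- list(`1` = contact_profile(mk(50, 450), ccfg, geo),
                `2` = contact_profile(mk(1, 499), ccfg, geo))
  outcomes <- data.frame(run = c(1, 2), label = c("captured", "failed"))
  s <- summarize_contacts(profs, outcomes, ccfg)
  expect_true(s$extended[s$label == "captured" & s$residue == "K8"])   # 0.10
  expect_false(s$extended[s$label == "failed" & s$residue == "K8"])    # 0.002
  expect_error(summarize_contacts(setNames(profs, c("1", "9")), outcomes),
               "run")
})

test_that("group summaries are invariant to run order", {
  top <- fixture_small_topology(geo)
  set.seed(91)
  profs <- lapply(1:4, function(i) contact_profile(
    fixture_trajectory(cbind(rnorm(30, 0, .6), rnorm(30, 0, .6),
                             runif(30, -0.3, 0.6)), top), ccfg, geo))
  names(profs) <- as.character(1:4)
  outcomes <- data.frame(run = 1:4,
                         label = c("captured", "failed", "captured",
                                   "failed"))
  s1 <- summarize_contacts(profs, outcomes, ccfg)
  s2 <- summarize_contacts(profs[c(3, 1, 4, 2)], outcomes, ccfg)
  expect_equal(s1[order(s1$label, s1$residue), ],
               s2[order(s2$label, s2$residue), ], ignore_attr = TRUE)
})

test_that("captured runs contact the vestibule; failed runs the cap/rim", {
  cfg <- generator_config()
  top <- build_surrogate_topology(geo)
  clf <- classification_config(geo)
  # mixed conditions: near release (mostly captured) and displaced release
  conds <- rbind(data.frame(height = 1, translation = 0),
                 data.frame(height = 3, translation = 2))
  runs <- expand.grid(cond = 1:2, rep = 1:30)
  profs <- list(); labels <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    cd <- conds[runs$cond[i], ]
    tr <- simulate_trajectory(list(height = cd$height,
                                   translation = cd$translation,
                                   orientation = "down", duration = 5000,
                                   seed = porecap:::derive_seed(7, i)),
                              geo, cfg, top)
    labels[i] <- classify_trajectory(tr, clf, geo)$label
    profs[[as.character(i)]] <- contact_profile(tr, ccfg, geo)
  }
  outcomes <- data.frame(run = seq_len(nrow(runs)), label = labels)
  s <- summarize_contacts(profs, outcomes, ccfg)
  zs <- zone_summary(s)
  cap <- zs[zs$label == "captured", ]
  expect_gt(sum(cap$fraction_of_extended[
    cap$zone %in% c("vestibule_interior", "vestibule_rim")]), 0.5)
  fail <- zs[zs$label == "failed", ]
  if (nrow(fail))
    expect_gt(sum(fail$fraction_of_extended[
      fail$zone %in% c("cap_surface", "vestibule_rim")]), 0.5)
})

test_that("hydrogen-bond proxy uses only N/O pairs at the tighter cutoff", {
  geo <- build_default_pore()
  # protein: one carbon residue ring and one asparagine with an N atom
  atoms <- data.frame(
    atom_id = 1:5,
    atom_name = c("CA", "CA", "CA", "ND2", "BAS"),
    element = c("C", "C", "C", "N", "N"),
    resid = c(rep("LYS", 3), "ASN", "CMP"),
    resno = c(8L, 8L, 8L, 47L, 1L),
    chain = c("A", "B", "C", "A", "X"),
    solute = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  top <- topology(atoms)
  # solute N sits 0.3 nm from the ASN nitrogen and 0.3 nm from a K8 carbon
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0.5, 0, 0),
               c(0, 0, 0))
  coords <- matrix(as.vector(t(ref)), nrow = 2, ncol = 15, byrow = TRUE)
  coords[2, 13:15] <- c(0.2, 0, 0)   # frame 2: solute next to both
  traj <- trajectory(top, coords, times = c(0, 10))
  hb <- hbond_series(traj, contact_config())
  expect_true(hb[2, "N47"])    # N...N at 0.3 nm <= 0.35
  expect_false(hb[2, "K8"])    # carbons are never donors/acceptors
  expect_false(hb[1, "N47"])   # 0.5 nm exceeds the 0.35 nm criterion
})
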