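test_that("BIDS file names compose correctly and reject bad labels", {
  expect_equal(bids_filename("K0109", "audiovisual", suffix = "eeg"),
               "sub-K0109_task-audiovisual_eeg")
  expect_equal(bids_filename("02", "audiovisual", session = "01",
                             suffix = "eeg"),
               "sub-02_ses-01_task-audiovisual_eeg")
  expect_equal(bids_filename("01", "oddball", suffix = "events", ext = "tsv"),
               "sub-01_task-oddball_events.tsv")
  expect_error(bids_filename("a b", "t", suffix = "eeg"), "invalid subject")
  expect_error(bids_filename("01", "odd-ball", suffix = "eeg"), "invalid task")
  expect_error(bids_filename("01", "t", suffix = "bold"), "suffix")
})

make_tiny_bids <- function(root, format = "brainvision", session = NULL) {
  cfg <- sim_config(n_subjects = 2, n_channels = 4, sfreq = 100,
                    n_trials = c(standard = 4, oddball = 2))
  subjects <- list()
  for (s in 1:2) {
    sim <- simulate_continuous(cfg, seed = s)
    subjects[[sprintf("sub-%02d", s)]] <- list(recording = sim$recording,
                                               events = sim$events)
  }
  ds <- list(
    name = "tiny synthetic oddball set",
    participants = data.frame(participant_id = c("sub-01", "sub-02"),
                              age = c(272L, NA), sex = c("f", "m")),
    participants_json = list(age = list(Description = "age", Units = "days"),
                             sex = list(Description = "sex")),
    subjects = subjects)
  write_bids_dataset(ds, root, task = "oddball", format = format,
                     session = session)
  ds
}

test_that("writing emits the expected tree and validation passes cleanly", {
  root <- withr::local_tempdir()
  make_tiny_bids(root)
  expect_true(file.exists(file.path(root, "dataset_description.json")))
  p <- read.delim(file.path(root, "participants.tsv"))
  expect_equal(nrow(p), 2)
  expect_true(file.exists(file.path(
    root, "sub-01", "eeg", "sub-01_task-oddball_eeg.vhdr")))
  expect_true(file.exists(file.path(
    root, "sub-01", "eeg", "sub-01_task-oddball_events.tsv")))
  expect_true(file.exists(file.path(
    root, "sub-01", "eeg", "sub-01_task-oddball_channels.tsv")))
  rep <- validate_bids_layout(root)
  expect_equal(sum(rep$severity == "error"), 0)
  # missing values serialised as n/a
  raw <- readLines(file.path(root, "participants.tsv"))
  expect_true(any(grepl("n/a", raw)))
  # every emitted eeg file matches the name grammar
  fls <- list.files(file.path(root, "sub-01", "eeg"))
  expect_true(all(grepl(erpcluster:::BIDS_NAME_RE, fls)))
})

test_that("the session level appears only when requested", {
  root <- withr::local_tempdir()
  make_tiny_bids(root, session = "01")
  expect_true(file.exists(file.path(
    root, "sub-01", "ses-01", "eeg", "sub-01_ses-01_task-oddball_eeg.vhdr")))
  expect_equal(sum(validate_bids_layout(root)$severity == "error"), 0)
})

test_that("write -> read round-trips participants, events and recordings", {
  for (fmt in c("brainvision", "tsv")) {
    root <- withr::local_tempdir()
    ds <- make_tiny_bids(root, format = fmt)
    back <- read_bids_dataset(root)
    expect_equal(back$participants$participant_id,
                 ds$participants$participant_id)
    expect_equal(back$participants$age, ds$participants$age)
    expect_equal(back$task, "oddball")
    for (id in names(ds$subjects)) {
      expect_equal(back$subjects[[id]]$events$onset,
                   ds$subjects[[id]]$events$onset, tolerance = 1e-9)
      expect_equal(back$subjects[[id]]$events$trial_type,
                   ds$subjects[[id]]$events$trial_type)
      expect_lt(max(abs(back$subjects[[id]]$recording$data -
                          ds$subjects[[id]]$recording$data)), 1e-9)
    }
    # write -> read -> write is byte-identical for the tabular files
    root2 <- withr::local_tempdir()
    ds2 <- ds
    for (id in names(ds2$subjects)) {
      ds2$subjects[[id]]$events <- back$subjects[[id]]$events
      ds2$subjects[[id]]$channels <- back$subjects[[id]]$channels
    }
    ds2$participants <- back$participants
    write_bids_dataset(ds2, root2, task = "oddball", format = fmt)
    for (rel in c("participants.tsv",
                  file.path("sub-01", "eeg", "sub-01_task-oddball_events.tsv"),
                  file.path("sub-01", "eeg", "sub-01_task-oddball_channels.tsv"))) {
      expect_identical(readLines(file.path(root2, rel)),
                       readLines(file.path(root, rel)))
    }
  }
})

test_that("reading degrades gracefully and rejects non-BIDS roots", {
  root <- withr::local_tempdir()
  expect_error(read_bids_dataset(root), "not a BIDS dataset")
  make_tiny_bids(root)
  unlink(file.path(root, "sub-02", "eeg", "sub-02_task-oddball_events.tsv"))
  back <- read_bids_dataset(root)
  expect_match(back$subjects[["sub-02"]]$warnings, "events")
  expect_null(back$subjects[["sub-02"]]$events)
  expect_false(is.null(back$subjects[["sub-01"]]$events))
})

test_that("curation errors name the missing field", {
  root <- withr::local_tempdir()
  ds <- list(name = "x",
             participants = data.frame(participant_id = "sub-01"),
             subjects = list("sub-01" = list(events = data.frame())))
  expect_error(write_bids_dataset(ds, root), "recording")
  ds2 <- list(participants = data.frame(participant_id = "sub-01"),
              subjects = list())
  expect_error(write_bids_dataset(ds2, root), "name")
})

test_that("validation flags naming, separation and dictionary problems", {
  root <- withr::local_tempdir()
  make_tiny_bids(root)
  # drop the task- entity from one file name
  eegdir <- file.path(root, "sub-01", "eeg")
  file.rename(file.path(eegdir, "sub-01_task-oddball_eeg.vhdr"),
              file.path(eegdir, "sub-01_audiovisual_eeg.vhdr"))
  rep <- validate_bids_layout(root)
  naming <- rep[rep$code == "NAMING", ]
  expect_equal(nrow(naming), 1)
  expect_match(naming$message, "task-")
  # derivative material inside a raw subject folder is a separation error
  file.rename(file.path(eegdir, "sub-01_audiovisual_eeg.vhdr"),
              file.path(eegdir, "sub-01_task-oddball_eeg.vhdr"))
  writeLines("x", file.path(eegdir, "sub-01_task-oddball_desc-clean_eeg.tsv"))
  rep2 <- validate_bids_layout(root)
  expect_equal(sum(rep2$code == "DERIVATIVES_IN_RAW"), 1)
  unlink(file.path(eegdir, "sub-01_task-oddball_desc-clean_eeg.tsv"))
  # age column without a dictionary entry is a warning, not an error
  unlink(file.path(root, "participants.json"))
  rep3 <- validate_bids_layout(root)
  expect_equal(sum(rep3$severity == "error"), 0)
  expect_true(any(rep3$code == "NO_DICTIONARY" & rep3$severity == "warning"))
  # empty directory is not a BIDS dataset
  rep4 <- validate_bids_layout(withr::local_tempdir())
  expect_true(any(rep4$code == "NO_DATASET_DESCRIPTION" &
                    rep4$severity == "error"))
})

test_that("BrainVision triplets round-trip data and markers", {
  set.seed(9)
  rec <- structure(list(data = matrix(stats::rnorm(3 * 500, sd = 2e-5), 3, 500),
                        sfreq = 250, channels = c("Cz", "Fz", "Pz"),
                        units = "V"), class = "erp_recording")
  ev <- data.frame(onset = c(0.4, 1.2), duration = c(0.5, 0.5),
                   trial_type = c("standard", "oddball"),
                   sample = c(100L, 300L))
  base <- file.path(withr::local_tempdir(), "rec")
  write_brainvision(rec, ev, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$recording$channels, rec$channels)
  expect_equal(back$recording$sfreq, 250)
  expect_lt(max(abs(back$recording$data - rec$data)), 1e-9)
  expect_equal(back$events$sample, ev$sample)
  expect_equal(back$events$trial_type, ev$trial_type)
})
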