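# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A latent cohort with explicit q values, for boundary cases.
manual_cohort <- function(q, age = 10, site = "RU", sex = "female") {
  n <- length(q)
  structure(
    data.frame(
      participant_id = sprintf("sub-%05d", seq_len(n)),
      site = rep_len(site, n), age = rep_len(age, n),
      sex = rep_len(sex, n), q = q, true_label = as.integer(q >= 0.5),
      stringsAsFactors = FALSE
    ),
    class = c("latent_cohort", "data.frame")
  )
}

# Bimodal banding-vs-clean phantom set for the deep QC smoke task.
phantom_set <- function(n, shape = c(32L, 32L, 32L), seed = 1L) {
  set.seed(seed)
  q <- c(stats::runif(ceiling(n / 2), 0, 0.35),
         stats::runif(floor(n / 2), 0.65, 1))
  q <- sample(q)
  vols <- lapply(seq_len(n), function(i) {
    generate_volume(q[i], shape = shape, seed = seed * 10000L + i)
  })
  list(volumes = vols, q = q, labels = as.integer(q >= 0.5))
}

# The deep-QC smoke fit at study scale (200 phantoms, 32^3), trained once
# and reused by the smoke, attribution and acceptance tests.
smoke_cnn_fit <- function() {
  fixture("smoke_cnn", function() {
    ph <- phantom_set(200, seed = 42)
    holdout <- seq_len(40)
    fit <- train_qc_cnn(
      build_qc_cnn(qc_network_spec(with_metrics = FALSE), seed = 1),
      ph$volumes[-holdout], ph$labels[-holdout],
      max_epochs = 2, batch_size = 8, seed = 1
    )
    list(fit = fit, phantoms = ph, holdout = holdout)
  })
}

# A tiny trained network (16^3) for cheap attribution checks.
tiny_cnn_fit <- function() {
  fixture("tiny_cnn", function() {
    ph <- phantom_set(24, shape = c(16L, 16L, 16L), seed = 7)
    fit <- train_qc_cnn(
      build_qc_cnn(qc_network_spec(with_metrics = FALSE,
                                   input_dim = c(16L, 16L, 16L)), seed = 2),
      ph$volumes, ph$labels, max_epochs = 2, batch_size = 6, seed = 2
    )
    list(fit = fit, phantoms = ph)
  })
}
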