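# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# tiny hand-built catalog: 3 SMH, 2 PE, 5 AE in two panels
toy_catalog <- function() {
  feature_catalog(data.frame(
    id = c("smh_a", "smh_b", "smh_c", "pe_d", "pe_e",
           "ae_f", "ae_g", "ae_h", "ae_i", "ae_j"),
    stage = c("SMH", "SMH", "SMH", "PE", "PE", rep("AE", 5)),
    domain = c(rep("binary", 5), rep("tri_level", 5)),
    panel = c(rep(NA, 5), "p1", "p1", "p1", "p2", "p2"),
    stringsAsFactors = FALSE))
}

# a well-formed record on the toy catalog
toy_record <- function() {
  patient_record(
    gender = "female", age = 6.5,
    chief_concerns = list(smh_a = "1"),
    extracted = list(smh_a = "1", smh_b = "0", pe_d = "1",
                     ae_f = "high", ae_g = "normal", ae_h = "low"),
    physician_sequence = c("smh_b", "pe_d", "p1"),
    diagnosis = list(constituents = "dis01", label_id = 1L))
}

# small default-world benchmark shared by slower statistical tests
shared_bench <- function() {
  memo("bench", make_benchmark(world_config(seed = 101L), 800L))
}

shared_D <- function() {
  memo("D", {
    b <- shared_bench()
    train_diagnosis_model(b$splits$train, b$world$catalog,
                          nrow(b$world$labels), hidden = 48L, epochs = 12L,
                          val_records = b$splits$validation, seed = 102L)
  })
}

shared_vae <- function() {
  memo("vae", {
    b <- shared_bench()
    train_vae(b$splits$train[1:300], b$world$catalog, d_z = 16L, d_e = 16L,
              hidden = 32L, epochs = 6L, seed = 103L)
  })
}
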