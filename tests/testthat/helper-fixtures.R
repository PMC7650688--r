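# Shared, lazily built heavyweight objects (built once per test run).

hap_test_env <- new.env()

test_fixture <- function() {
  if (is.null(hap_test_env$fx)) hap_test_env$fx <- load_case_fixture()
  hap_test_env$fx
}

test_panel <- function() {
  if (is.null(hap_test_env$panel)) hap_test_env$panel <- hap_panel()
  hap_test_env$panel
}

test_model <- function() toy_transcript_model()

# fixture records annotated against the bundled synthetic snapshots
test_fixture_annotated <- function() {
  if (is.null(hap_test_env$ann)) {
    fx <- test_fixture()
    hap_test_env$ann <- annotate_variants(fx$variants, fx$snapshots)
  }
  hap_test_env$ann
}
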