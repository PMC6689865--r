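# Shared objects for the suite: the rule table is loaded once (it is static
# data), and a default configuration is reused across files.
rules <- ionstate::load_default_rules()
cfg_default <- ionstate::protonation_config()

# Independent interval-overlap oracle: two closed intervals overlap iff the
# larger lower bound does not exceed the smaller upper bound.
oracle_action <- function(pka, ph) {
  if (max(pka[1], ph[1]) <= min(pka[2], ph[2])) return("both")
  if (pka[2] < ph[1]) "deprotonate" else "protonate"
}

# Independent required-set/outcome oracle, written directly from the
# correct/excess/incorrect definitions: membership comparison by explicit
# enumeration over the two monoprotic states.
oracle_outcome <- function(pka, emitted, ph_min, ph_max) {
  required <- if (pka < ph_min) "deprotonated"
  else if (pka > ph_max) "protonated"
  else c("deprotonated", "protonated")
  states <- c("deprotonated", "protonated")
  req_in <- states %in% required
  emit_in <- states %in% emitted
  if (identical(req_in, emit_in)) return("correct")
  if (all(!req_in | emit_in)) return("excess")
  "incorrect"
}
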