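# Quiet package logging during the suite.
op <- options(bloodmet.log_level = "quiet")
withr::defer(options(op), teardown_env())
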