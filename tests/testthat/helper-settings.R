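# Report every failure instead of aborting the run once the progress
# reporter's default failure cap is reached: the Monte-Carlo reproduction
# blocks compare many table cells at once and later files must still run.
options(testthat.progress.max_fails = 100)
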