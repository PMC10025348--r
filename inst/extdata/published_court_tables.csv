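table,conditioning,conditioning_level,response_level,count
judge_defendant,judge,angry,angry,10
judge_defendant,judge,angry,neutral,1
judge_defendant,judge,angry,fear,10
judge_defendant,judge,neutral,angry,8
judge_defendant,judge,neutral,neutral,19
judge_defendant,judge,neutral,fear,2
plaintiff_defendant,plaintiff,angry,angry,7
plaintiff_defendant,plaintiff,angry,neutral,3
plaintiff_defendant,plaintiff,angry,fear,6
plaintiff_defendant,plaintiff,neutral,angry,10
plaintiff_defendant,plaintiff,neutral,neutral,16
plaintiff_defendant,plaintiff,neutral,fear,4
plaintiff_defendant,plaintiff,fear,angry,1
plaintiff_defendant,plaintiff,fear,neutral,1
plaintiff_defendant,plaintiff,fear,fear,2
court_logic,court,angry,logical,1
court_logic,court,angry,non-logical,15
court_logic,court,neutral,logical,28
court_logic,court,neutral,non-logical,4
court_logic,court,fear,logical,1
court_logic,court,fear,non-logical,1
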