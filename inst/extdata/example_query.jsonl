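{"conversation_id":"q001","utterances":[{"utterance_id":"q001_u00","speaker_id":"S1","text":"Where have you been?","position":0,"gold_label":"unknown"},{"utterance_id":"q001_u01","speaker_id":"S2","text":"Oh! I wanted to hurt myself.","position":1,"gold_label":"unknown"},{"utterance_id":"q001_u02","speaker_id":"S1","text":"What happened to you?","position":2,"gold_label":"unknown"},{"utterance_id":"q001_u03","speaker_id":"S2","text":"I was broken, it's shocking.","position":3,"gold_label":"unknown"}]}
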