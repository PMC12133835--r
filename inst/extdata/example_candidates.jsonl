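{"expl_id":"d001_e1","text":"the speaker says they wanted to hurt themselves and feels broken which signals sadness and low mood","demo_id":"d001","generator":"example"}
{"expl_id":"d001_e2","text":"the speaker reports feeling broken and shocking hurt pointing to persistent sadness","demo_id":"d001","generator":"example"}
{"expl_id":"d001_e3","text":"the conversation mentions a happy afternoon walking by the river with contentment","demo_id":"d001","generator":"example"}
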