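{"demo_id":"d001","text":"lately nothing brings me joy and the sadness will not lift","label":"depression","source":"example"}
{"demo_id":"d002","text":"we spent a happy afternoon walking by the river","label":"normal","source":"example"}
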