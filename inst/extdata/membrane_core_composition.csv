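head_group,core_class,percent
PG,DEG,66.2
PG,AEG,17.0
PG,DAG,9.3
PG,MEG,7.4
PE,DAG,54.0
PE,AEG,7.5
PE,DEG,25.0
PE,MEG,13.5
PE,MAG,0.2
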