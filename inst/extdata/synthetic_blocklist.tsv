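variant_id	confounder
rs000901	insomnia
rs000902	anxiety
rs000903	obesity
rs000903	alcohol_intake
rs000904	smoking
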