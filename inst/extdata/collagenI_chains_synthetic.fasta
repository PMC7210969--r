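>COL1A1 synthetic rat-like collagen alpha-1(I) chain
QLSYGDEKKTAGISVPGAPGKDGooGRoGDEGTSGKNGARGLoGAPGSIGoSGNVGPAGASGAoGoPGENGoLGPNGAAGVoGAoGPNGVPGPAGMDGASGMFGkEGKKGEHGVDGPoGTIGoNGRQGLoGPoGSFGSVGVYGPIGoAGPPGDNGKoGoLGAoGPPGPPGAQGKoGPPGVMGPPGRTGQHGTEGoDGAPGPRGoLGEAGSPGDAGooGREGANGASGNoGIoGQPGADGPAGPAGDIGPoGRVGETGFSGQRGoCGoTGPRGSYGEKGNYGVLGISGNVGEoGAPGoPGDoGoPGooGNAGSTGoAGRRGooGYPGToGVAGALGEEGPDGoEGIPGoEGEAGAoGIPGVLGooGoEGoDGoAGLAGoQGooGPAGooGSoGoEGoLGADGIVGPoGoSGRoGATGPSGLKGPDGFAGFEGNRGoPGoPGAPGPoGRSGKoGAYGSTGoAGANGoPGooGRoGoRGVDGooGPQGSoGYKGAPGRSGEAGDEGPLGPKGPSGVVGooGPPGEKGPPGSNGoPGVNGLPGDSGToGEPGERGTDGPPGLoGPPGEEGKRGSVGoSGAEGAWGAVGFPGRAGSPGNSGDPGoNGEoGoTGHSGoPGEPGALGPQGSFGoLGToGLRGAPGDMGRoGAoGIFGPAGKAGELGTKGVQGDAGAKGSAGTAGTFGRRGAFGVPGooGooGTRGEoGKKGoAGVAGVoGoRGTDGKPGooGDRGoEGQRGAoGKPGoPGPSGRPGASGoPGPSGENGKoGoAGARGAoGVSGARGPPGPSGAoGVVGPPGADGAKGPPGIDGoAGYDGVKGREGEPGDAGPPGVEGEAGoQGDQGPoGRTGRPGPKGARGPTGPLGPWGDoGLoGQRGPSGALGLEGPoGAAGoAGNPGAFGDEGSVGKAGAAGVPGATGAoGPEGAAGToGRoGEPGoAGDPGPoGVFGkRGEYGYDGPVGMEGIDGPoGAoGYoGAPGLoGDVGoWGPPGEPGPVGoKGEoGEoGPPGSTGAKGoTGNAGoMGYGDEKSTAGISVPQLSYGDEKKTAG
>COL1A2 synthetic rat-like collagen alpha-2(I) chain
QLSYGDEKKTAGISVPGPSGooGAVGooGADGPoGoKGPoGDDGSPGAEGTDGoAGAAGILGAPGHLGoAGLEGNEGDTGLoGLoGVTGDoGEPGDRGRPGoLGkEGNVGKoGooGPQGAoGSPGoRGSDGPPGoPGFEGKSGADGSoGQRGDPGFEGPDGRPGooGoLGTAGEHGYoGSPGVQGERGRRGSSGALGQDGLoGELGPAGEoGAPGRAGPPGoEGLNGRPGoVGEKGADGAVGoSGPPGPSGPKGASGASGLTGAoGARGPQGQoGTKGRRGKRGoPGPDGKoGIoGPPGRoGoTGQRGSNGAAGTKGPAGENGPPGEHGAoGPAGMDGAPGVTGoPGoQGPAGoSGToGNLGAKGoAGLoGPPGPPGRNGVEGooGPoGoRGVQGAPGKLGTLGLAGPTGooGoPGATGDMGQLGRAGAoGAPGToGTIGPoGLLGAPGIYGLAGADGERGAoGKEGoAGLoGVTGHoGEoGTFGoPGNKGQLGPPGToGDAGKPGFoGSSGVKGPFGRAGooGoPGARGSPGPPGPKGTNGAIGAPGPPGYTGoPGVQGPPGDPGLoGAAGPPGVPGoAGKIGASGSRGILGoQGAQGSPGLHGRNGQoGDAGPKGSLGRoGTRGNoGYFGQHGoPGoNGPPGITGERGRAGVPGoDGKVGNoGAAGATGRVGIPGoNGPPGPVGELGEAGPPGoYGRoGAoGPKGoRGPTGSEGRRGNoGDDGIPGPSGARGPLGPEGPQGLAGEHGNTGKRGoNGPAGENGooGPYGToGVSGLPGQAGHoGTAGKPGAoGKoGRNGoKGPAGPoGoVGPPGVTGLMGoNGQAGoQGPQGRPGPTGMAGQHGPAGRoGEKGDAGAPGAMGoEGPTGAAGEoGPKGMPGAPGAKGPRGRTGLIGoRGEVGATGLAGKKGoSGQQGPDGYVGoAGAPGIPGYDGPFGoFGAQGkYGFFGIoGoPGSAGLIGQSGPPGoAGPDGooGPoGPVGPDGAHGEoGPoGPPGPKGPRGoSGAPGLDGDDGDQGYGDEKSTAGISVPQLSYGDEKKTAG
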